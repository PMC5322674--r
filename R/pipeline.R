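#' Plant a variant with explicit genotypes and annotations
#'
#' Scenario-level helper: overwrites the genotypes of one site across named
#' samples and forces its annotation fields, so that a variant with a known
#' segregation pattern and filter behaviour exists in the set. Samples not
#' named keep their simulated genotypes.
#'
#' @param variants a [variant_set()].
#' @param site integer site index.
#' @param genotypes named integer vector (0/1/2/NA) of per-sample overrides.
#' @param annotations named list of annotation column overrides.
#' @return the modified variant set.
#' @export
plant_variant <- function(variants, site, genotypes = NULL,
                          annotations = NULL) {
  stopifnot(site >= 1, site <= n_sites(variants))
  for (id in names(genotypes)) variants$geno[site, id] <- genotypes[[id]]
  for (col in names(annotations)) {
    if (!col %in% names(variants$sites)) stop("unknown annotation: ", col)
    variants$sites[site, col] <- annotations[[col]]
  }
  variants
}

# gene map used by the demo scenarios: 100-kb buckets stand in for genes
bucket_gene_map <- function(variants, width = 100000L) {
  sprintf("G%s_%06d", variants$sites$chrom,
          as.integer((variants$sites$pos - 1) %/% width))
}

# the three-segment deletion plan of the contiguous-deletion demo, using the
# event's published hg19 breakpoints on 15q11.2-q13.1
pws_deletion_plan <- function(carrier = "p5") {
  data.frame(start = c(22749401, 23608601, 28897601),
             end = c(23198800, 28566000, 28992600),
             carrier = carrier, origin = "paternal", de_novo = TRUE,
             copies = 1L, stringsAsFactors = FALSE)
}

#' Run a packaged demonstration scenario
#'
#' Three end-to-end scenarios mirror the analysis archetypes the toolkit is
#' built for, each on synthetic data with recorded truth:
#'
#' * `"pws_demo"` — a nine-sequenced-member, three-generation pedigree in
#'   which the proband carries a de novo three-segment heterozygous deletion
#'   on the paternal haplotype (~5.5 Mb total) and his mother is
#'   unsequenced. The pipeline detects the deletion from binned depth,
#'   computes segment/gap arithmetic, infers the paternal origin from
#'   Mendelian-inconsistency informative sites, and prioritizes the deletion
#'   interval against the proband's 21-term HPO profile using a planted
#'   knowledge base.
#' * `"hh_demo"` — an affected founder homozygous for a planted pathogenic
#'   recessive variant; the cascade must keep it on the recessive track.
#' * `"dysautonomia_demo"` — several dominant-model variants of mixed
#'   annotation quality; only the fully supported ones survive the cascade.
#'
#' @param preset scenario name.
#' @param seed integer seed controlling every random draw.
#' @param n_sites variant grid size (scenario default if `NULL`).
#' @return a report bundle (list) whose contents depend on the scenario; all
#'   bundles carry `scenario`, `seed`, `pedigree`, `variants`, `truth`.
#' @export
run_scenario <- function(preset = c("pws_demo", "hh_demo",
                                    "dysautonomia_demo"),
                         seed = 1L, n_sites = NULL) {
  preset <- match.arg(preset)
  switch(preset,
         pws_demo = scenario_pws(seed, n_sites %||% 10000L),
         hh_demo = scenario_hh(seed, n_sites %||% 2000L),
         dysautonomia_demo = scenario_dys(seed, n_sites %||% 2000L))
}

scenario_pws <- function(seed, n_sites) {
  ped <- pedigree_preset("three_generation_9")
  spec <- simulation_spec(
    seed = seed, n_sites = n_sites, chrom = "chr15", chrom_length = 3e7,
    pedigree = ped, mean_coverage = 40, bin_size = 100L,
    genotype_error_rate = 0.005,
    deletions = pws_deletion_plan("p5"),
    # the unaffected brother shares the proband's maternal haplotype over
    # the region, as the high real-data consistency fractions imply
    force_transmission = list(p5 = list(mother = 1L), b5 = list(mother = 1L)))
  sim <- generate_pedigree_genotypes(spec)
  sim$variants <- annotate_variants(sim$variants, spec, sim$truth)

  track <- simulate_depth(spec)
  gmean0 <- mean(track$depth)
  calls1 <- call_deletions(track, gmean0)
  gmean <- estimate_genome_mean(track, calls1)
  calls <- call_deletions(track, gmean)
  segs <- segment_arithmetic(calls)
  segs$segments$depth_ratio <- vapply(seq_len(nrow(segs$segments)),
    function(i) depth_ratio(segs$segments[i, ], track, gmean), numeric(1))

  informative <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i)
    classify_informative_sites(
      sim$variants,
      list(chrom = calls$chrom[i], start = calls$start[i],
           end = calls$end[i]),
      father_id = "u3", sibling_id = "b5", proband_id = "p5")))
  origin <- call_origin(informative)

  kb <- generate_knowledge_base(
    seed = seed,
    planted = list(disease = "PLANTED_SYNDROME", n_genes = 15, n_terms = 9,
                   chrom = "chr15", region = c(23608601, 28566000)))
  set.seed(seed + 3L)
  terms <- c(kb$truth$terms,
             sample(setdiff(unique(kb$disease_term$hpo_id), kb$truth$terms),
                    12L))
  bg_genes <- setdiff(unique(kb$gene_disease$gene), kb$truth$genes)
  candidates <- list(
    genes = sort(sample(bg_genes, min(10L, length(bg_genes)))),
    intervals = data.frame(id = sprintf("DEL%d", seq_len(nrow(calls))),
                           chrom = calls$chrom, start = calls$start,
                           end = calls$end, stringsAsFactors = FALSE))
  prior <- score_entities(terms, candidates, kb)
  target <- candidates$intervals$id[which.max(
    candidates$intervals$end - candidates$intervals$start)]

  bundle <- list(scenario = "pws_demo", seed = seed, spec = spec,
                 pedigree = ped, variants = sim$variants, truth = sim$truth,
                 track = track, genome_mean = gmean, calls = calls,
                 segments = segs, informative = informative, origin = origin,
                 kb = kb, terms = terms, candidates = candidates,
                 prioritization = prior, target = target)
  class(bundle) <- "scenario_bundle"
  bundle
}

# branch pedigree shared by the two small-variant demos: founder couple and
# three children; `hh` marks the recessive-disease phenotype, `dys` the
# dominant one segregating through the mother
branch_pedigree <- function() {
  Pedigree(id = c("f2", "m2", "d3", "s3", "s4"),
           father = c(NA, NA, "f2", "f2", "f2"),
           mother = c(NA, NA, "m2", "m2", "m2"),
           sex = c("male", "female", "female", "male", "female"),
           affected = c(FALSE, TRUE, FALSE, FALSE, FALSE),
           hh = c(FALSE, TRUE, FALSE, FALSE, FALSE),
           dys = c(FALSE, TRUE, TRUE, TRUE, TRUE))
}

scenario_hh <- function(seed, n_sites, affected_override = NULL) {
  ped <- branch_pedigree()
  if (!is.null(affected_override)) ped$hh <- affected_override
  spec <- simulation_spec(seed = seed, n_sites = n_sites, chrom = "chr6",
                          chrom_length = 5e6, pedigree = ped,
                          genotype_error_rate = 0.005)
  sim <- generate_pedigree_genotypes(spec)
  planted_site <- n_sites %/% 2L
  sim$variants <- annotate_variants(sim$variants, spec, sim$truth,
                                    planted_pathogenic = planted_site)
  sim$variants <- plant_variant(
    sim$variants, planted_site,
    genotypes = c(m2 = 2L, f2 = 0L, d3 = 1L, s3 = 1L, s4 = 1L),
    annotations = list(af_db1 = 0.02, af_db2 = 0.03))
  gene_map <- bucket_gene_map(sim$variants)
  part <- partition_by_model(sim$variants, ped, "hh", gene_map)
  trace <- run_filter_cascade(part, sim$variants, "autosomal_recessive")
  bundle <- list(scenario = "hh_demo", seed = seed, pedigree = ped,
                 variants = sim$variants, truth = sim$truth,
                 planted_site = planted_site, partition = part,
                 trace = trace,
                 planted_recovered = planted_site %in% trace$final_kept)
  class(bundle) <- "scenario_bundle"
  bundle
}

scenario_dys <- function(seed, n_sites, n_planted = 7L) {
  ped <- branch_pedigree()
  spec <- simulation_spec(seed = seed, n_sites = n_sites, chrom = "chr12",
                          chrom_length = 5e6, pedigree = ped,
                          genotype_error_rate = 0.005)
  sim <- generate_pedigree_genotypes(spec)
  set.seed(seed + 4L)
  planted <- sort(sample.int(n_sites, n_planted + 4L))
  survivors <- planted[seq_len(n_planted)]
  decoys <- planted[-seq_len(n_planted)]
  sim$variants <- annotate_variants(sim$variants, spec, sim$truth,
                                    planted_pathogenic = planted)
  dominant_gt <- c(m2 = 1L, d3 = 1L, s3 = 1L, s4 = 1L, f2 = 0L)
  for (s in planted)
    sim$variants <- plant_variant(sim$variants, s, genotypes = dominant_gt,
                                  annotations = list(af_db1 = 0.001,
                                                     af_db2 = 0.001))
  # decoys each violate one rule of the cascade
  sim$variants <- plant_variant(sim$variants, decoys[1],
                                annotations = list(af_db1 = 0.02))
  sim$variants <- plant_variant(sim$variants, decoys[2],
                                annotations = list(cadd = 12))
  sim$variants <- plant_variant(sim$variants, decoys[3],
                                annotations = list(callers = "gatk"))
  sim$variants <- plant_variant(sim$variants, decoys[4],
                                annotations = list(p_adj = 0.5))
  gene_map <- bucket_gene_map(sim$variants)
  part <- partition_by_model(sim$variants, ped, "dys", gene_map)
  trace <- run_filter_cascade(part, sim$variants, "autosomal_dominant")
  bundle <- list(scenario = "dysautonomia_demo", seed = seed, pedigree = ped,
                 variants = sim$variants, truth = sim$truth,
                 planted_survivors = survivors, decoys = decoys,
                 partition = part, trace = trace,
                 n_dominant_survivors = length(trace$final_kept))
  class(bundle) <- "scenario_bundle"
  bundle
}

#' Render a human-readable scenario report
#'
#' Every number printed is recomputed from the bundle contents, so
#' regenerating the report from a saved bundle is byte-identical.
#'
#' @param bundle a bundle from [run_scenario()].
#' @return character vector of report lines (also printed with
#'   `cat` when `quiet = FALSE`).
#' @param quiet suppress printing.
#' @export
scenario_report <- function(bundle, quiet = FALSE) {
  ln <- c(sprintf("scenario: %s (seed %d)", bundle$scenario, bundle$seed))
  if (bundle$scenario == "pws_demo") {
    segs <- bundle$segments
    ln <- c(ln, sprintf("deletion segments called: %d", nrow(segs$segments)))
    for (i in seq_len(nrow(segs$segments))) {
      s <- segs$segments[i, ]
      ln <- c(ln, sprintf("  %s:%d-%d size %d bp depth-ratio %.3f",
                          s$chrom, s$start, s$end, s$size, s$depth_ratio))
    }
    ln <- c(ln,
            sprintf("total deleted: %d bp", segs$total_size),
            sprintf("gaps: %s bp", paste(segs$gaps, collapse = ", ")),
            sprintf("informative sites: %d (A: %d/%d, B: %d/%d)",
                    bundle$origin$n_A + bundle$origin$n_B,
                    bundle$origin$n_A_consistent, bundle$origin$n_A,
                    bundle$origin$n_B_consistent, bundle$origin$n_B),
            sprintf("combined consistency: %.4f", bundle$origin$frac_combined),
            sprintf("origin call: %s", bundle$origin$call))
    tgt <- bundle$prioritization[
      bundle$prioritization$entity == bundle$target, ]
    ln <- c(ln, sprintf("target interval %s: score %.4f tier %s",
                        bundle$target, tgt$score, tgt$tier))
  } else {
    tr <- bundle$trace
    ln <- c(ln, sprintf("model: %s, %d sites in", tr$model, length(tr$input)))
    for (st in tr$stages)
      ln <- c(ln, sprintf("  %s: kept %d removed %d", st$stage, st$n_kept,
                          st$n_removed))
    ln <- c(ln, sprintf("final kept: %d", length(tr$final_kept)))
    if (!is.null(bundle$planted_site))
      ln <- c(ln, sprintf("planted site recovered: %s",
                          bundle$planted_recovered))
    if (!is.null(bundle$planted_survivors))
      ln <- c(ln, sprintf("planted survivors expected: %d",
                          length(bundle$planted_survivors)))
  }
  if (!quiet) cat(paste(ln, collapse = "\n"), "\n", sep = "")
  invisible(ln)
}
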