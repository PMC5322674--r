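#' Built-in pedigree layouts
#'
#' `"trio"`: father, mother, one affected child. `"quad"`: trio plus an
#' unaffected sibling. `"three_generation_9"`: a three-generation family with
#' nine sequenced members and two unsequenced ones — a founder couple whose
#' two children head two nuclear families; in the second family the mother is
#' unsequenced, so her branch carries an affected proband and an unaffected
#' brother whose maternal genotypes are never observed. This is the layout the
#' parent-of-origin machinery is designed for: the deletion carrier's mother
#' contributes alleles to the simulation but no genotype column to the output.
#'
#' @param layout one of `"trio"`, `"quad"`, `"three_generation_9"`.
#' @return a [Pedigree].
#' @export
pedigree_preset <- function(layout = c("three_generation_9", "trio", "quad")) {
  layout <- match.arg(layout)
  switch(layout,
    trio = Pedigree(
      id = c("father", "mother", "child"),
      father = c(NA, NA, "father"), mother = c(NA, NA, "mother"),
      sex = c("male", "female", "male"),
      affected = c(FALSE, FALSE, TRUE)),
    quad = Pedigree(
      id = c("father", "mother", "child", "sib"),
      father = c(NA, NA, "father", "father"),
      mother = c(NA, NA, "mother", "mother"),
      sex = c("male", "female", "male", "female"),
      affected = c(FALSE, FALSE, TRUE, FALSE)),
    three_generation_9 = Pedigree(
      id     = c("gm1",    "gf1",  "m2",     "f2",   "u3",   "um2",
                 "d3",     "s3",   "s4",     "p5",   "b5"),
      father = c(NA,       NA,     "gf1",    NA,     "gf1",  NA,
                 "f2",     "f2",   "f2",     "u3",   "u3"),
      mother = c(NA,       NA,     "gm1",    NA,     "gm1",  NA,
                 "m2",     "m2",   "m2",     "um2",  "um2"),
      sex    = c("female", "male", "female", "male", "male", "female",
                 "female", "male", "female", "male", "male"),
      affected  = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, TRUE, FALSE),
      sequenced = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE,
                    TRUE, TRUE, TRUE, TRUE, TRUE)))
}

#' Simulation specification
#'
#' Declares everything the generator needs: the pedigree, the variant grid,
#' the founder allele-frequency law (Beta), mean sequencing coverage, the
#' depth bin width, the per-genotype error rate, the per-site recombination
#' probability, and the planted-deletion plan.
#'
#' @param seed integer RNG seed; a fixed seed yields byte-identical outputs.
#' @param n_sites number of bi-allelic variant sites.
#' @param chrom chromosome label.
#' @param chrom_length chromosome length in bp.
#' @param pedigree a [Pedigree] (default [pedigree_preset()] trio).
#' @param af_alpha,af_beta Beta-law parameters for founder allele
#'   frequencies; the default (0.5, 0.5) skews mass toward frequency extremes
#'   like a site-frequency spectrum.
#' @param mean_coverage genome-wide mean depth (X) of a diploid region.
#' @param bin_size depth bin width (bp).
#' @param genotype_error_rate probability that an emitted genotype is
#'   replaced by a uniformly chosen different genotype; must be in [0, 0.5).
#' @param recomb_rate per-site probability that a transmitted haplotype
#'   switches between the parent's two haplotypes. Default 0: whole
#'   haplotypes transmit, which preserves the haplotype-scale signal that
#'   parent-of-origin inference needs.
#' @param deletions data frame of planted deletions with columns `start`,
#'   `end`, `carrier`, `origin` ("paternal"/"maternal"), `de_novo` (logical)
#'   and optionally `copies` (remaining copy number, default 1).
#' @param force_transmission named list fixing which parental haplotype (1 or
#'   2) a child receives, e.g. `list(p5 = c(mother = 1))`. Only meaningful
#'   with `recomb_rate = 0`; used by demo scenarios to make siblings share a
#'   maternal haplotype as the real data show.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(seed = 1L, n_sites = 10000L, chrom = "chr15",
                            chrom_length = 3e7,
                            pedigree = pedigree_preset("trio"),
                            af_alpha = 0.5, af_beta = 0.5,
                            mean_coverage = 40, bin_size = 100L,
                            genotype_error_rate = 0.005,
                            recomb_rate = 0,
                            deletions = NULL,
                            force_transmission = NULL) {
  if (genotype_error_rate < 0 || genotype_error_rate >= 0.5)
    stop("genotype_error_rate must lie in [0, 0.5)")
  if (recomb_rate < 0 || recomb_rate > 0.5)
    stop("recomb_rate must lie in [0, 0.5]")
  validate_pedigree(pedigree)
  if (!is.null(deletions) && nrow(deletions)) {
    stopifnot(all(c("start", "end", "carrier", "origin") %in%
                    names(deletions)))
    if (is.null(deletions$de_novo)) deletions$de_novo <- TRUE
    if (is.null(deletions$copies)) deletions$copies <- 1L
    if (any(deletions$start > deletions$end) ||
        any(deletions$start < 1) || any(deletions$end > chrom_length))
      stop("deletion segments must satisfy 1 <= start <= end <= chrom_length")
    d <- deletions[order(deletions$start), ]
    if (nrow(d) > 1L && any(d$start[-1] <= d$end[-nrow(d)]))
      stop("deletion segments overlap")
    if (!all(deletions$carrier %in% pedigree$id))
      stop("deletion carrier not in pedigree")
    deletions <- d
  }
  structure(list(seed = as.integer(seed), n_sites = as.integer(n_sites),
                 chrom = chrom, chrom_length = chrom_length,
                 pedigree = pedigree, af_alpha = af_alpha, af_beta = af_beta,
                 mean_coverage = mean_coverage,
                 bin_size = as.integer(bin_size),
                 genotype_error_rate = genotype_error_rate,
                 recomb_rate = recomb_rate, deletions = deletions,
                 force_transmission = force_transmission),
            class = "simulation_spec")
}

#' Generate pedigree genotypes
#'
#' Draws per-site founder allele frequencies from the configured Beta law,
#' founder haplotypes as Bernoulli(AF), and child haplotypes by transmission
#' (one haplotype per parent, switching between the parent's haplotypes with
#' probability `recomb_rate` per site). Planted deletions are applied as
#' hemizygous genotype overrides (see [plant_deletions()]) before genotype
#' errors are injected at the configured rate. Everything needed to audit
#' the realization — haplotypes, transmission map, the injected-error log,
#' founder AFs and the deletion plan — is returned as the truth record.
#'
#' @param spec a [simulation_spec()].
#' @return list with `pedigree`, `variants` (a [variant_set()] over all
#'   pedigree members, sequenced or not) and `truth` (list: `af`,
#'   `haplotypes`, `transmission`, `errors`, `deletions`, `positions`).
#' @export
generate_pedigree_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  ped <- spec$pedigree
  half <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(half))
    stop("simulation requires both parents known or neither; offending ",
         "member(s): ", paste(ped$id[half], collapse = ", "))
  set.seed(spec$seed)
  n <- spec$n_sites
  pos <- sort(sample.int(spec$chrom_length, n))
  af <- stats::rbeta(n, spec$af_alpha, spec$af_beta)

  order_ids <- pedigree_order(ped)
  haps <- list()          # per id: n x 2 matrix (col 1 paternal, 2 maternal)
  transmission <- list()  # per non-founder id: list(father=, mother=) 1/2

  draw_transmission <- function(child_id, parent_label) {
    forced <- spec$force_transmission[[child_id]][[parent_label]]
    if (!is.null(forced) && spec$recomb_rate == 0)
      return(rep(as.integer(forced), n))
    start <- sample(1:2, 1L)
    if (spec$recomb_rate == 0) return(rep(start, n))
    switches <- stats::rbinom(n - 1L, 1L, spec$recomb_rate)
    1L + (start - 1L + c(0L, cumsum(switches))) %% 2L
  }

  for (id in order_ids) {
    row <- ped[ped$id == id, ]
    if (is.na(row$father)) {
      haps[[id]] <- cbind(stats::rbinom(n, 1L, af), stats::rbinom(n, 1L, af))
    } else {
      tf <- draw_transmission(id, "father")
      tm <- draw_transmission(id, "mother")
      fh <- haps[[row$father]]; mh <- haps[[row$mother]]
      haps[[id]] <- cbind(fh[cbind(seq_len(n), tf)],
                          mh[cbind(seq_len(n), tm)])
      transmission[[id]] <- list(father = tf, mother = tm)
    }
  }

  geno <- vapply(ped$id, function(id) haps[[id]][, 1] + haps[[id]][, 2],
                 integer(n))

  truth <- list(af = af, positions = pos, haplotypes = haps,
                transmission = transmission,
                deletions = spec$deletions,
                errors = data.frame(site = integer(0), sample = character(0),
                                    from = integer(0), to = integer(0)))

  sites <- data.frame(chrom = spec$chrom, pos = pos,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  vs <- variant_set(sites, geno)

  if (!is.null(spec$deletions) && nrow(spec$deletions)) {
    planted <- plant_deletions(vs, ped, spec$deletions, truth)
    vs <- planted$variants
    truth <- planted$truth
  }

  # genotype errors: symmetric swap to a uniformly chosen different genotype
  e <- spec$genotype_error_rate
  if (e > 0) {
    hit <- which(matrix(stats::runif(n * nrow(ped)) < e, nrow = n))
    hit <- hit[!is.na(vs$geno[hit])]
    if (length(hit)) {
      old <- vs$geno[hit]
      shift <- sample(1:2, length(hit), replace = TRUE)
      new <- (old + shift) %% 3L
      vs$geno[hit] <- new
      truth$errors <- data.frame(
        site = ((hit - 1L) %% n) + 1L,
        sample = ped$id[((hit - 1L) %/% n) + 1L],
        from = old, to = new, stringsAsFactors = FALSE)
    }
  }

  list(pedigree = ped, variants = vs, truth = truth)
}

#' Plant hemizygous deletions into a genotype matrix
#'
#' Within each deleted segment the carrier's observed genotype collapses to
#' homozygosity for the allele transmitted by the non-deleted parent: for a
#' paternal-origin deletion, the maternal transmitted allele doubled. The
#' emitted genotype stays an ordinary diploid code — hemizygosity is hidden,
#' as a small-variant caller would report it — which is exactly what makes
#' downstream origin inference non-trivial. Sites outside the segments are
#' untouched, and no parent genotype is modified (de novo events are absent
#' from both parents by construction).
#'
#' @param variants a [variant_set()].
#' @param pedigree the [Pedigree] the matrix columns belong to.
#' @param deletions deletion plan data frame (see [simulation_spec()]).
#' @param truth a truth record carrying `haplotypes` and `transmission` for
#'   the carrier (as produced by [generate_pedigree_genotypes()]).
#' @return list with modified `variants` and updated `truth` (the plan is
#'   recorded under `truth$deletions`).
#' @export
plant_deletions <- function(variants, pedigree, deletions, truth) {
  pos <- variants$sites$pos
  for (i in seq_len(nrow(deletions))) {
    d <- deletions[i, ]
    if (!d$carrier %in% pedigree$id) stop("unknown carrier: ", d$carrier)
    trans <- truth$transmission[[d$carrier]]
    if (is.null(trans))
      stop("carrier '", d$carrier, "' is a founder without simulated ",
           "parents; parental origin '", d$origin, "' cannot be planted")
    idx <- which(pos >= d$start & pos <= d$end)
    if (!length(idx)) next
    surviving_parent <- switch(as.character(d$origin),
                               paternal = "mother", maternal = "father",
                               stop("origin must be 'paternal' or 'maternal'"))
    parent_id <- pedigree[[surviving_parent]][pedigree$id == d$carrier]
    hap_choice <- trans[[surviving_parent]][idx]
    allele <- truth$haplotypes[[parent_id]][cbind(idx, hap_choice)]
    copies <- if (is.null(d$copies) || is.na(d$copies)) 1L else d$copies
    variants$geno[idx, d$carrier] <-
      if (copies == 0L) NA_integer_ else 2L * allele
  }
  truth$deletions <- deletions
  list(variants = variants, truth = truth)
}

#' Simulate a binned depth track
#'
#' Per-bin depth is drawn from a Poisson law with mean
#' `mean_coverage * copy_number / 2`; bins inside a heterozygous deletion
#' (copy number 1) therefore average half the genome-wide mean, and a
#' homozygous deletion (copy 0) yields exactly zero. Bins partially
#' overlapping a deletion use the length-weighted copy number.
#'
#' @param spec a [simulation_spec()].
#' @param deletions deletion plan rows to apply to this genome (default: the
#'   plan in `spec`); pass `NULL` or an empty frame for a diploid track.
#' @param seed RNG seed (default derived from `spec$seed`).
#' @return a [depth_track()].
#' @export
simulate_depth <- function(spec, deletions = spec$deletions,
                           seed = spec$seed + 1L) {
  stopifnot(spec$bin_size >= 1)
  set.seed(seed)
  nbins <- floor(spec$chrom_length / spec$bin_size)
  cn <- rep(2, nbins)
  if (!is.null(deletions) && nrow(deletions)) {
    bin_start <- (seq_len(nbins) - 1) * spec$bin_size + 1
    bin_end <- bin_start + spec$bin_size - 1
    for (i in seq_len(nrow(deletions))) {
      d <- deletions[i, ]
      copies <- if (is.null(d$copies) || is.na(d$copies)) 1 else d$copies
      ov <- pmax(0, pmin(bin_end, d$end) - pmax(bin_start, d$start) + 1)
      cn <- cn - (ov / spec$bin_size) * (2 - copies)
    }
  }
  depth_track(spec$chrom, spec$bin_size,
              stats::rpois(nbins, spec$mean_coverage * cn / 2))
}

#' Annotate simulated variants
#'
#' Populates the annotation record every downstream filter consumes. The two
#' population AF fields are finite-sample perturbations of the truth AF
#' (binomial resampling at reference-panel scale), impact class and
#' deleteriousness score come from configured categorical/mixture laws,
#' ClinVar-like labels are mostly "none" with a small benign fraction, caller
#' support is a random 1-3 subset of four caller labels, and the QC fields
#' (alt-allele coverage, chi-square, adjusted p) are drawn from simple
#' parametric laws. Sites listed in `planted_pathogenic` are forced to a
#' fully filter-passing pathogenic annotation.
#'
#' @param variants a [variant_set()].
#' @param spec the originating [simulation_spec()].
#' @param truth the matching truth record (source of per-site truth AFs).
#' @param planted_pathogenic integer site indices to annotate as planted
#'   pathogenic variants.
#' @param seed RNG seed (default derived from `spec$seed`).
#' @return the variant set with all annotation columns populated.
#' @export
annotate_variants <- function(variants, spec, truth,
                              planted_pathogenic = integer(0),
                              seed = spec$seed + 2L) {
  set.seed(seed)
  n <- n_sites(variants)
  af <- truth$af
  s <- variants$sites
  s$af_db1 <- stats::rbinom(n, 5008L, af) / 5008
  s$af_db2 <- stats::rbinom(n, 121412L, af) / 121412
  s$impact <- sample(IMPACT_LEVELS, n, replace = TRUE,
                     prob = c(0.85, 0.10, 0.05))
  s$is_lof <- as.numeric(s$impact == "high" & stats::runif(n) < 0.4)
  s$cadd <- ifelse(stats::runif(n) < 0.05,
                   pmax(0, stats::rnorm(n, 22, 4)),
                   stats::rgamma(n, shape = 2, scale = 3))
  s$clinvar <- sample(CLINVAR_LEVELS, n, replace = TRUE,
                      prob = c(0.002, 0.002, 0.001, 0.002, 0.043, 0.95))
  caller_pool <- c("gatk", "freebayes", "scalpel", "repeatseq")
  ncall <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  s$callers <- vapply(ncall, function(k)
    paste(sort(sample(caller_pool, k)), collapse = ","), character(1))
  s$alt_coverage <- stats::rpois(n, spec$mean_coverage / 2)
  s$chi2 <- stats::rchisq(n, df = 1)
  s$p_adj <- stats::runif(n)
  if (length(planted_pathogenic)) {
    i <- planted_pathogenic
    s$clinvar[i] <- "pathogenic"
    s$impact[i] <- "high"
    s$is_lof[i] <- 1
    s$cadd[i] <- stats::runif(length(i), 20, 35)
    s$p_adj[i] <- stats::runif(length(i), 0.001, 0.04)
    s$callers[i] <- "freebayes,gatk"
    s$alt_coverage[i] <- pmax(5L, s$alt_coverage[i])
  }
  variants$sites <- s
  variants
}

#' Generate a synthetic gene/disease/phenotype knowledge base
#'
#' Builds weighted gene-disease and disease-term link tables plus gene-gene
#' links labelled "biosystem" or "family", with one planted disease: a
#' contiguous cluster of genes placed inside a designated genomic region,
#' linked to one disease which carries a characteristic HPO-term profile —
#' the synthetic analogue of a contiguous-gene-deletion syndrome. The planted
#' disease's genes, terms and region are recorded in `$truth`.
#'
#' @param n_genes,n_diseases,n_terms background dimensions.
#' @param planted list with `disease` (label), `n_genes`, `n_terms`,
#'   `chrom`, `region` (`c(start, end)` where the gene cluster is placed).
#' @param seed RNG seed.
#' @param chrom_length background gene coordinate span.
#' @return a `KnowledgeBase` (see [read_kb()]) with an extra `truth` element.
#' @export
generate_knowledge_base <- function(n_genes = 60, n_diseases = 12,
                                    n_terms = 40,
                                    planted = list(disease = "PLANTED_SYNDROME",
                                                   n_genes = 15, n_terms = 9,
                                                   chrom = "chr15",
                                                   region = c(23608601, 28566000)),
                                    seed = 1L, chrom_length = 3e7) {
  stopifnot(planted$n_genes >= 1)
  set.seed(seed)
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  diseases <- c(planted$disease,
                sprintf("DISEASE%02d", seq_len(n_diseases - 1L)))
  terms <- sprintf("HP:%07d", sample.int(9999999L, n_terms))

  p_genes <- genes[seq_len(planted$n_genes)]
  p_terms <- terms[seq_len(planted$n_terms)]

  # coordinates: planted cluster tiled across the planted region, background
  # genes scattered outside it
  span <- planted$region[2] - planted$region[1] + 1
  step <- floor(span / planted$n_genes)
  p_start <- planted$region[1] + (seq_len(planted$n_genes) - 1L) * step
  bg <- setdiff(genes, p_genes)
  bg_start <- sample.int(chrom_length - 50000L, length(bg))
  # keep background genes out of the planted region
  inside <- bg_start > (planted$region[1] - 50000) & bg_start < planted$region[2]
  bg_start[inside] <- ((bg_start[inside] + planted$region[2]) %% (chrom_length - 50000L)) + 1L
  inside <- bg_start > (planted$region[1] - 50000) & bg_start < planted$region[2]
  bg_start[inside] <- pmax(1L, planted$region[1] - 200000L - seq_len(sum(inside)) * 10000L)
  gene_tab <- rbind(
    data.frame(gene = p_genes, chrom = planted$chrom, start = p_start,
               end = p_start + pmin(step - 1L, 20000L),
               stringsAsFactors = FALSE),
    data.frame(gene = bg, chrom = planted$chrom, start = bg_start,
               end = bg_start + 20000L, stringsAsFactors = FALSE))

  gd <- data.frame(gene = p_genes, disease = planted$disease,
                   weight = stats::runif(planted$n_genes, 0.6, 1),
                   stringsAsFactors = FALSE)
  dt <- data.frame(disease = planted$disease, hpo_id = p_terms,
                   weight = stats::runif(planted$n_terms, 0.6, 1),
                   stringsAsFactors = FALSE)
  for (d in diseases[-1]) {
    dg <- sample(bg, sample(3:8, 1))
    gd <- rbind(gd, data.frame(gene = dg, disease = d,
                               weight = stats::runif(length(dg), 0.1, 1)))
    dtm <- sample(setdiff(terms, p_terms), sample(2:6, 1))
    dt <- rbind(dt, data.frame(disease = d, hpo_id = dtm,
                               weight = stats::runif(length(dtm), 0.1, 1)))
  }
  n_gg <- max(10L, n_genes %/% 3L)
  g1 <- sample(genes, n_gg, replace = TRUE)
  g2 <- sample(genes, n_gg, replace = TRUE)
  keep <- g1 != g2
  gg <- data.frame(gene1 = g1[keep], gene2 = g2[keep],
                   relation = sample(c("biosystem", "family"), sum(keep),
                                     replace = TRUE),
                   weight = stats::runif(sum(keep), 0.1, 1),
                   stringsAsFactors = FALSE)
  kb <- list(gene_disease = gd, disease_term = dt, gene_gene = gg,
             genes = gene_tab,
             truth = list(disease = planted$disease, genes = p_genes,
                          terms = p_terms, chrom = planted$chrom,
                          region = planted$region))
  class(kb) <- "KnowledgeBase"
  validate_kb(kb)
  kb
}
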