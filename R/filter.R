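MODEL_NAMES <- c("autosomal_dominant", "autosomal_recessive", "de_novo",
                 "compound_het", "x_linked_dominant")

#' Partition variants by disease inheritance model
#'
#' Evaluates each variant against five segregation models for the affected
#' set defined by `phenotype_label` (a logical column of the pedigree):
#'
#' * `de_novo`: some affected member is het or hom-alt while both of their
#'   genotyped parents are hom-ref.
#' * `autosomal_dominant`: every genotyped affected member carries at least
#'   one alternate allele and no genotyped unaffected member carries any.
#' * `autosomal_recessive`: every genotyped affected member is hom-alt, no
#'   genotyped unaffected member is hom-alt, and every genotyped parent of an
#'   affected member carries the allele.
#' * `compound_het`: two distinct heterozygous variants in one gene in an
#'   affected member, on opposite parental haplotypes when transmission
#'   phasing is possible, flagged `unphased` otherwise; pairs phased to the
#'   same haplotype are rejected.
#' * `x_linked_dominant`: the dominant logic restricted to X-chromosome
#'   sites, with het calls in males accepted as hemizygous-alt.
#'
#' Models may overlap. A variant can satisfy several.
#'
#' @param variants a [variant_set()].
#' @param pedigree a [Pedigree].
#' @param phenotype_label name of the logical affected-status column
#'   (default `"affected"`).
#' @param gene_map character vector mapping each site to a gene id (needed
#'   for the compound-het model; `NULL` disables that model).
#' @param max_unaffected_carriers allowed genotyped unaffected carriers in
#'   the dominant models (default 0 = full penetrance).
#' @return a `model_partition` list: per-model integer site indices (for
#'   `compound_het`, a data frame of site pairs with a `phase` column), plus
#'   `affected`/`unaffected` sample sets used.
#' @export
partition_by_model <- function(variants, pedigree,
                               phenotype_label = "affected",
                               gene_map = NULL,
                               max_unaffected_carriers = 0L) {
  if (is.null(pedigree[[phenotype_label]]))
    stop("unknown phenotype label: ", phenotype_label)
  samples <- colnames(variants$geno)
  ped <- pedigree[pedigree$id %in% samples, ]
  affected <- ped$id[ped[[phenotype_label]]]
  unaffected <- ped$id[!ped[[phenotype_label]]]
  if (!length(affected)) stop("no affected member for label: ", phenotype_label)
  g <- variants$geno
  ns <- nrow(g)
  on_x <- variants$sites$chrom %in% c("X", "chrX")
  males <- ped$id[ped$sex == "male"]

  carries <- function(ids, hemi = FALSE) {
    # per-site count of members in `ids` carrying >= 1 alt (NA = not genotyped)
    if (!length(ids)) return(list(carry = rep(0L, ns), all_carry = rep(TRUE, ns)))
    sub <- g[, ids, drop = FALSE]
    list(carry = rowSums(sub >= 1L, na.rm = TRUE),
         genotyped = rowSums(!is.na(sub)))
  }

  ## de novo: per affected child with both parents genotyped
  dn_sites <- integer(0)
  dn_detail <- list()
  for (a in affected) {
    prow <- ped[ped$id == a, ]
    if (is.na(prow$father) || is.na(prow$mother)) next
    if (!(prow$father %in% samples) || !(prow$mother %in% samples)) next
    hit <- which(!is.na(g[, a]) & g[, a] >= 1L &
                 !is.na(g[, prow$father]) & g[, prow$father] == 0L &
                 !is.na(g[, prow$mother]) & g[, prow$mother] == 0L)
    dn_sites <- union(dn_sites, hit)
    dn_detail[[a]] <- hit
  }

  ## dominant core (reused for autosomal and X-linked)
  aff_g <- g[, affected, drop = FALSE]
  una_g <- g[, unaffected, drop = FALSE]
  aff_carry_ok <- rowSums(!(aff_g >= 1L), na.rm = TRUE) == 0L &
    rowSums(!is.na(aff_g)) > 0L
  una_carriers <- if (length(unaffected))
    rowSums(una_g >= 1L, na.rm = TRUE) else rep(0L, ns)
  dominant <- aff_carry_ok & una_carriers <= max_unaffected_carriers

  ad_sites <- which(dominant & !on_x)

  ## X-linked dominant: male het on X treated as hemizygous alt (carrier);
  ## the carrier test is the same dosage >= 1, so the dominant mask applies
  xl_sites <- which(dominant & on_x)

  ## recessive
  aff_hom <- rowSums(!(aff_g == 2L), na.rm = TRUE) == 0L &
    rowSums(!is.na(aff_g)) > 0L
  una_hom <- if (length(unaffected))
    rowSums(una_g == 2L, na.rm = TRUE) else rep(0L, ns)
  parents_ok <- rep(TRUE, ns)
  for (a in affected) {
    prow <- ped[ped$id == a, ]
    for (p in c(prow$father, prow$mother)) {
      if (!is.na(p) && p %in% samples) {
        pg <- g[, p]
        parents_ok <- parents_ok & (is.na(pg) | pg >= 1L)
      }
    }
  }
  ar_sites <- which(aff_hom & una_hom == 0L & parents_ok & !on_x)

  ## compound het
  ch <- data.frame(site1 = integer(0), site2 = integer(0),
                   gene = character(0), carrier = character(0),
                   phase = character(0), stringsAsFactors = FALSE)
  if (!is.null(gene_map)) {
    stopifnot(length(gene_map) == ns)
    for (a in affected) {
      het <- which(!is.na(g[, a]) & g[, a] == 1L)
      if (length(het) < 2L) next
      prow <- ped[ped$id == a, ]
      fid <- if (!is.na(prow$father) && prow$father %in% samples) prow$father else NA
      mid <- if (!is.na(prow$mother) && prow$mother %in% samples) prow$mother else NA
      origin <- vapply(het, function(i) {
        fcar <- if (!is.na(fid)) !is.na(g[i, fid]) && g[i, fid] >= 1L else NA
        mcar <- if (!is.na(mid)) !is.na(g[i, mid]) && g[i, mid] >= 1L else NA
        if (isTRUE(fcar) && isFALSE(mcar)) "paternal"
        else if (isTRUE(mcar) && isFALSE(fcar)) "maternal"
        else "unknown"
      }, character(1))
      by_gene <- split(seq_along(het), gene_map[het])
      pair_frames <- lapply(by_gene, function(grp) {
        if (length(grp) < 2L) return(NULL)
        pairs <- utils::combn(grp, 2L)
        o1 <- origin[pairs[1, ]]; o2 <- origin[pairs[2, ]]
        cis <- o1 != "unknown" & o2 != "unknown" & o1 == o2
        if (all(cis)) return(NULL)
        keep <- which(!cis)
        data.frame(site1 = het[pairs[1, keep]], site2 = het[pairs[2, keep]],
                   gene = gene_map[het[pairs[1, keep]]], carrier = a,
                   phase = ifelse(o1[keep] == "unknown" |
                                    o2[keep] == "unknown",
                                  "unphased", "trans"),
                   stringsAsFactors = FALSE)
      })
      pair_frames <- pair_frames[!vapply(pair_frames, is.null, logical(1))]
      if (length(pair_frames))
        ch <- rbind(ch, do.call(rbind, pair_frames))
    }
  }

  structure(list(autosomal_dominant = ad_sites,
                 autosomal_recessive = ar_sites,
                 de_novo = sort(dn_sites),
                 compound_het = ch,
                 x_linked_dominant = xl_sites,
                 de_novo_by_child = dn_detail,
                 affected = affected, unaffected = unaffected),
            class = "model_partition")
}

#' @export
print.model_partition <- function(x, ...) {
  for (m in MODEL_NAMES) {
    n <- if (m == "compound_het") nrow(x[[m]]) else length(x[[m]])
    cat(sprintf("  %-20s %d %s\n", m, n,
                if (m == "compound_het") "pairs" else "sites"))
  }
  invisible(x)
}

new_trace_stage <- function(label, input, kept, reasons = NULL) {
  stage <- list(stage = label, n_input = length(input),
                n_kept = length(kept), n_removed = length(input) - length(kept),
                kept = kept, removed = setdiff(input, kept),
                reasons = reasons)
  stopifnot(stage$n_kept + stage$n_removed == stage$n_input)
  stage
}

#' Population allele-frequency filter
#'
#' Variants under dominant-type models (autosomal dominant, de novo,
#' X-linked dominant) are kept only when both population AF fields are at or
#' below 0.01; the cut-off relaxes to 0.05 for the recessive-type models
#' (autosomal recessive, compound het). The rule excludes strictly greater
#' values, so a recessive variant at exactly 0.05 survives. A missing AF is
#' treated as 0: absent from the database means never observed, i.e. rare.
#'
#' @param sites integer site indices to filter.
#' @param variants a [variant_set()].
#' @param model the inheritance model the sites were assigned under.
#' @return a filter-trace stage (list with `kept`, `removed`, counts).
#' @export
af_filter <- function(sites, variants, model = "autosomal_dominant") {
  cutoff <- if (model %in% c("autosomal_recessive", "compound_het"))
    0.05 else 0.01
  af1 <- variants$sites$af_db1[sites]
  af2 <- variants$sites$af_db2[sites]
  af1[is.na(af1)] <- 0; af2[is.na(af2)] <- 0
  keep <- af1 <= cutoff & af2 <= cutoff
  new_trace_stage(paste0("af_filter[", model, "]"), sites, sites[keep],
                  reasons = stats::setNames(
                    rep("population_af", sum(!keep)), sites[!keep]))
}

#' Evidence filter
#'
#' Keeps a variant only when all four evidence criteria hold: (1) support by
#' at least two calling pipelines, (2) adjusted p-value strictly below 0.05,
#' (3) medium or high predicted impact, or a loss-of-function flag, and
#' (4) deleteriousness score strictly greater than 15. Each removal records
#' the first failing criterion.
#'
#' @inheritParams af_filter
#' @export
evidence_filter <- function(sites, variants) {
  s <- variants$sites
  caller_str <- as.character(s$callers[sites])
  caller_str[is.na(caller_str)] <- ""
  ncallers <- vapply(strsplit(caller_str, ",", fixed = TRUE),
                     function(x) length(x[nzchar(x)]), integer(1))
  p <- s$p_adj[sites]; imp <- s$impact[sites]
  lof <- !is.na(s$is_lof[sites]) & s$is_lof[sites] > 0
  cadd <- s$cadd[sites]
  fail <- rep(NA_character_, length(sites))
  fail[is.na(fail) & ncallers < 2L] <- "caller_concordance"
  fail[is.na(fail) & (is.na(p) | p >= 0.05)] <- "p_adj"
  fail[is.na(fail) & !(imp %in% c("medium", "high") | lof)] <- "impact"
  fail[is.na(fail) & (is.na(cadd) | cadd <= 15)] <- "cadd"
  keep <- is.na(fail)
  new_trace_stage("evidence_filter", sites, sites[keep],
                  reasons = stats::setNames(fail[!keep], sites[!keep]))
}

#' ClinVar rescue report
#'
#' Collects every site whose clinical-significance label is pathogenic,
#' probably-pathogenic, mixed or drug-response into a dedicated report,
#' independent of whether the model-based cascade removed it. This is a
#' parallel reporting track, not an un-removal: the cascade outputs are
#' unchanged, and each rescued site carries flags saying whether it survived
#' the cascade.
#'
#' @param variants a [variant_set()].
#' @param trace a `filter_trace` (see [run_filter_cascade()]) or `NULL`.
#' @return data frame: `site`, `clinvar`, `in_final_kept`.
#' @export
clinvar_rescue <- function(variants, trace = NULL) {
  rescue_labels <- c("pathogenic", "probably_pathogenic", "mixed",
                     "drug_response")
  idx <- which(variants$sites$clinvar %in% rescue_labels)
  final_kept <- if (!is.null(trace)) trace$final_kept else integer(0)
  data.frame(site = idx, clinvar = variants$sites$clinvar[idx],
             in_final_kept = idx %in% final_kept,
             stringsAsFactors = FALSE)
}

#' INDEL QC filter for assembly-based caller records
#'
#' Applies only to records carrying the `scalpel` caller label: a record is
#' removed when its alternate-allele coverage is below five AND its
#' chi-square score exceeds 10.8 — the conjunction as printed in the
#' originating benchmark; set `conjunction = FALSE` for the disjunctive
#' (stricter) reading. Records from other callers are untouched.
#'
#' @inheritParams af_filter
#' @param conjunction combine the two conditions with AND (default) or OR.
#' @export
indel_qc_filter <- function(sites, variants, conjunction = TRUE) {
  s <- variants$sites
  caller_str <- as.character(s$callers[sites])
  caller_str[is.na(caller_str)] <- ""
  is_scalpel <- grepl("scalpel", caller_str)
  ac <- s$alt_coverage[sites]; chi <- s$chi2[sites]
  low_cov <- !is.na(ac) & ac < 5
  high_chi <- !is.na(chi) & chi > 10.8
  bad <- is_scalpel & if (conjunction) low_cov & high_chi
                      else low_cov | high_chi
  new_trace_stage("indel_qc", sites, sites[!bad],
                  reasons = stats::setNames(
                    rep("scalpel_qc", sum(bad)), sites[bad]))
}

#' Run the full variant filtering cascade for one inheritance model
#'
#' Chains the INDEL QC, allele-frequency and evidence stages over the sites
#' a model partition assigned to `model`, collecting a conserving trace:
#' at every stage `kept + removed = input`.
#'
#' @param partition a `model_partition` from [partition_by_model()].
#' @param variants a [variant_set()].
#' @param model one of the five model names.
#' @return a `filter_trace` list: `model`, `stages`, `final_kept`, and the
#'   `rescue` report from [clinvar_rescue()].
#' @export
run_filter_cascade <- function(partition, variants, model) {
  stopifnot(model %in% MODEL_NAMES)
  sites <- if (model == "compound_het")
    sort(unique(c(partition$compound_het$site1, partition$compound_het$site2)))
  else partition[[model]]
  stages <- list()
  cur <- sites
  for (f in list(function(x) indel_qc_filter(x, variants),
                 function(x) af_filter(x, variants, model),
                 function(x) evidence_filter(x, variants))) {
    st <- f(cur)
    stages[[length(stages) + 1L]] <- st
    cur <- st$kept
  }
  trace <- structure(list(model = model, input = sites, stages = stages,
                          final_kept = cur),
                     class = "filter_trace")
  trace$rescue <- clinvar_rescue(variants, trace)
  trace
}

#' @export
print.filter_trace <- function(x, ...) {
  cat(sprintf("Filter trace [%s]: %d site(s) in\n", x$model, length(x$input)))
  for (st in x$stages)
    cat(sprintf("  %-28s kept %5d  removed %5d\n",
                st$stage, st$n_kept, st$n_removed))
  cat(sprintf("  final kept: %d\n", length(x$final_kept)))
  invisible(x)
}
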