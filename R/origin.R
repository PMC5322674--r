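#' Classify Mendelian-inconsistency informative sites
#'
#' Within a candidate hemizygous region, a site is informative for
#' paternal-deletion testing when the father is homozygous and an unaffected
#' full sibling is heterozygous (all three genotypes non-missing). Two
#' classes arise: class A (father hom-ref, sibling het) where a proband
#' carrying only a maternal allele is expected hom-alt, and class B (father
#' hom-alt, sibling het) where the expected observation is hom-ref — each a
#' Mendelian violation given the father's genotype, and therefore evidence
#' that the paternal allele is deleted. A heterozygous proband genotype is
#' inconsistent with hemizygosity in both classes and is counted against the
#' call, never dropped.
#'
#' @param variants a [variant_set()].
#' @param region region (string or list, see [parse_region()]).
#' @param father_id,sibling_id,proband_id sample ids present in the
#'   genotype matrix.
#' @return data frame: `site`, `pos`, `class` ("A"/"B"), `proband_gt`,
#'   `consistent` (logical).
#' @export
classify_informative_sites <- function(variants, region, father_id,
                                       sibling_id, proband_id) {
  reg <- parse_region(region)
  fa <- geno_of(variants, father_id)
  si <- geno_of(variants, sibling_id)
  pr <- geno_of(variants, proband_id)
  s <- variants$sites
  in_reg <- s$chrom == reg$chrom & s$pos >= reg$start & s$pos <= reg$end
  ok <- in_reg & !is.na(fa) & !is.na(si) & !is.na(pr) &
    (fa == 0L | fa == 2L) & si == 1L
  idx <- which(ok)
  cls <- ifelse(fa[idx] == 0L, "A", "B")
  consistent <- ifelse(cls == "A", pr[idx] == 2L, pr[idx] == 0L)
  data.frame(site = idx, pos = s$pos[idx], class = cls,
             proband_gt = pr[idx], consistent = consistent,
             stringsAsFactors = FALSE)
}

#' Call the parental origin of a hemizygous deletion
#'
#' Aggregates informative-site counts into per-class and combined
#' consistency fractions and calls `paternal_deleted` when the combined
#' fraction reaches `min_frac` over at least `min_sites` sites. The mirrored
#' maternal test (roles of mother and father swapped) is evaluated from
#' `maternal_informative` when mother genotypes exist; with the mother
#' unsequenced only paternal-deletion versus no-call is decidable.
#' Insufficient data yields `no_call`, never an error.
#'
#' @param informative output of [classify_informative_sites()] with
#'   father/sibling roles (paternal-deletion test).
#' @param min_sites minimum informative sites for a call.
#' @param min_frac minimum combined consistency fraction. The defaults
#'   (50 sites, 0.8) tolerate genotyping error while rejecting deletion-free
#'   regions, where the fraction collapses toward the allele-frequency
#'   baseline.
#' @param maternal_informative optional mirrored classification (mother
#'   homozygous, sibling het) for the maternal-deletion test.
#' @return an `OriginCallResult` list: counts `n_A`, `n_A_consistent`,
#'   `n_B`, `n_B_consistent`, fractions `frac_A`, `frac_B`, `frac_combined`,
#'   the `call`, and the thresholds used.
#' @export
call_origin <- function(informative, min_sites = 50L, min_frac = 0.8,
                        maternal_informative = NULL) {
  tally <- function(inf) {
    a <- inf$class == "A"
    list(n_A = sum(a), n_A_consistent = sum(a & inf$consistent),
         n_B = sum(!a), n_B_consistent = sum(!a & inf$consistent))
  }
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  t1 <- tally(informative)
  res <- list(
    n_A = t1$n_A, n_A_consistent = t1$n_A_consistent,
    n_B = t1$n_B, n_B_consistent = t1$n_B_consistent,
    frac_A = frac(t1$n_A_consistent, t1$n_A),
    frac_B = frac(t1$n_B_consistent, t1$n_B),
    frac_combined = frac(t1$n_A_consistent + t1$n_B_consistent,
                         t1$n_A + t1$n_B),
    min_sites_used = min_sites, threshold_used = min_frac)
  paternal_pass <- (t1$n_A + t1$n_B) >= min_sites &&
    !is.na(res$frac_combined) && res$frac_combined >= min_frac
  maternal_pass <- FALSE
  if (!is.null(maternal_informative)) {
    t2 <- tally(maternal_informative)
    fc2 <- frac(t2$n_A_consistent + t2$n_B_consistent, t2$n_A + t2$n_B)
    maternal_pass <- (t2$n_A + t2$n_B) >= min_sites &&
      !is.na(fc2) && fc2 >= min_frac
    res$frac_combined_maternal <- fc2
  }
  res$call <- if (paternal_pass) "paternal_deleted"
              else if (maternal_pass) "maternal_deleted"
              else "no_call"
  class(res) <- "OriginCallResult"
  res
}

#' @export
print.OriginCallResult <- function(x, ...) {
  cat("Parental-origin call:", x$call, "\n")
  cat(sprintf("  class A (father hom-ref, sib het): %d/%d consistent (%s)\n",
              x$n_A_consistent, x$n_A, pct(x$frac_A)))
  cat(sprintf("  class B (father hom-alt, sib het): %d/%d consistent (%s)\n",
              x$n_B_consistent, x$n_B, pct(x$frac_B)))
  cat(sprintf("  combined: %s (threshold %.2f over >= %d sites)\n",
              pct(x$frac_combined), x$threshold_used, x$min_sites_used))
  invisible(x)
}

pct <- function(x) if (is.na(x)) "NA" else sprintf("%.1f%%", 100 * x)

#' Scan for Mendelian violations per child
#'
#' A violation is any child genotype impossible under bi-allelic Mendelian
#' transmission given the genotyped parents: with both parents available the
#' full trio table is used; with a single genotyped parent, only opposite
#' homozygosity (parent hom-ref with child hom-alt, or the reverse) is
#' impossible. Sites with a missing genotype in the child or in every
#' genotyped parent are not evaluated.
#'
#' @param variants a [variant_set()].
#' @param pedigree a [Pedigree]; children with at least one genotyped parent
#'   are scanned.
#' @return data frame per child: `child`, `n_eval`, `n_violations`, `rate`,
#'   with per-child violated site indices in the `violations` attribute.
#' @export
mendelian_violation_scan <- function(variants, pedigree) {
  samples <- colnames(variants$geno)
  kids <- pedigree$id[(!is.na(pedigree$father) & pedigree$father %in% samples) |
                      (!is.na(pedigree$mother) & pedigree$mother %in% samples)]
  kids <- intersect(kids, samples)
  if (!length(kids)) stop("no parent-child pair with genotype data")
  viol_list <- list()
  out <- data.frame(child = character(0), n_eval = integer(0),
                    n_violations = integer(0), rate = numeric(0))
  for (k in kids) {
    prow <- pedigree[pedigree$id == k, ]
    cg <- variants$geno[, k]
    fg <- if (!is.na(prow$father) && prow$father %in% samples)
      variants$geno[, prow$father] else rep(NA_integer_, length(cg))
    mg <- if (!is.na(prow$mother) && prow$mother %in% samples)
      variants$geno[, prow$mother] else rep(NA_integer_, length(cg))
    eval_ok <- !is.na(cg) & (!is.na(fg) | !is.na(mg))
    v <- trio_violation(fg, mg, cg) & eval_ok
    viol_list[[k]] <- which(v)
    out <- rbind(out, data.frame(
      child = k, n_eval = sum(eval_ok), n_violations = sum(v),
      rate = if (sum(eval_ok)) sum(v) / sum(eval_ok) else NA_real_))
  }
  attr(out, "violations") <- viol_list
  out
}

# vectorized impossibility test; NA parent treated as unconstrained
trio_violation <- function(fg, mg, cg) {
  # allele sets: hom_ref {0}, het {0,1}, hom_alt {1}; NA -> {0,1}
  can_give <- function(g, allele) {
    out <- if (allele == 0L) g <= 1L else g >= 1L
    out[is.na(g)] <- TRUE
    out
  }
  possible <- rep(FALSE, length(cg))
  for (a in 0:1) for (b in 0:1) {
    if (!any(!possible)) break
    match_ <- !is.na(cg) & cg == (a + b) & can_give(fg, a) & can_give(mg, b)
    possible <- possible | match_
  }
  !is.na(cg) & !possible
}
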