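# Independent oracles and small fixtures used across the suite.

# variant set with explicit genotype rows; geno: matrix or data.frame-ish
make_vs <- function(geno, chrom = "chr1", pos = NULL, ...) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n <- nrow(geno)
  sites <- data.frame(chrom = chrom,
                      pos = if (is.null(pos)) seq_len(n) * 100L else pos,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) sites[[nm]] <- extra[[nm]]
  variant_set(sites, geno)
}

# Exhaustive truth table for informative-site classification: for every
# (father, sibling, proband) genotype triple, what the classifier must say.
# Written as plain conditionals, independent of the implementation.
informative_truth_table <- function() {
  rows <- expand.grid(father = 0:2, sibling = 0:2, proband = 0:2)
  rows$informative <- rows$father %in% c(0L, 2L) & rows$sibling == 1L
  rows$class <- ifelse(!rows$informative, NA_character_,
                       ifelse(rows$father == 0L, "A", "B"))
  rows$consistent <- ifelse(!rows$informative, NA,
                            ifelse(rows$class == "A",
                                   rows$proband == 2L, rows$proband == 0L))
  rows
}

# Naive single-site inheritance-model evaluator for a fixed quad pedigree
# (father, mother, child1 affected, child2 unaffected), written directly
# from the model definitions.
naive_models_quad <- function(g, on_x = FALSE) {
  fa <- g[["father"]]; mo <- g[["mother"]]
  c1 <- g[["child1"]]; c2 <- g[["child2"]]
  models <- character(0)
  carries <- function(x) !is.na(x) && x >= 1L
  dominant <- carries(c1) && !carries(c2) && !carries(fa) && !carries(mo)
  if (dominant && !on_x) models <- c(models, "autosomal_dominant")
  if (dominant && on_x) models <- c(models, "x_linked_dominant")
  recessive <- !is.na(c1) && c1 == 2L &&
    !(!is.na(c2) && c2 == 2L) && !(!is.na(fa) && fa == 2L) &&
    !(!is.na(mo) && mo == 2L) &&
    (is.na(fa) || fa >= 1L) && (is.na(mo) || mo >= 1L)
  if (recessive && !on_x) models <- c(models, "autosomal_recessive")
  if (!is.na(c1) && c1 >= 1L && !is.na(fa) && fa == 0L &&
      !is.na(mo) && mo == 0L)
    models <- c(models, "de_novo")
  models
}

# Recompute every observed genotype from the truth record alone:
# haplotype sums, then hemizygous deletion overrides, then the error log.
observed_from_truth <- function(sim) {
  ped <- sim$pedigree
  truth <- sim$truth
  n <- length(truth$positions)
  obs <- vapply(ped$id, function(id)
    truth$haplotypes[[id]][, 1] + truth$haplotypes[[id]][, 2], integer(n))
  dels <- truth$deletions
  if (!is.null(dels)) {
    for (i in seq_len(nrow(dels))) {
      d <- dels[i, ]
      idx <- which(truth$positions >= d$start & truth$positions <= d$end)
      surv <- if (d$origin == "paternal") "mother" else "father"
      pid <- ped[[surv]][ped$id == d$carrier]
      hap <- truth$transmission[[d$carrier]][[surv]][idx]
      allele <- truth$haplotypes[[pid]][cbind(idx, hap)]
      obs[idx, d$carrier] <- if (!is.null(d$copies) && d$copies == 0L)
        NA_integer_ else 2L * allele
    }
  }
  e <- truth$errors
  for (i in seq_len(nrow(e))) obs[e$site[i], e$sample[i]] <- e$to[i]
  obs
}

# Pascal-recurrence binomial coefficient (independent of n_combinations)
pascal_choose <- function(n, k) {
  row <- 1
  for (i in seq_len(n)) row <- c(1, utils::head(row, -1) + row[-1], 1)[1:(i + 1)]
  row[k + 1]
}

# Hand-built 5-gene knowledge base with weights chosen for easy manual sums.
tiny_kb <- function() {
  kb <- list(
    gene_disease = data.frame(
      gene = c("G1", "G2", "G3", "G4"),
      disease = c("D1", "D1", "D2", "D2"),
      weight = c(0.8, 0.5, 1.0, 0.4), stringsAsFactors = FALSE),
    disease_term = data.frame(
      disease = c("D1", "D1", "D2"),
      hpo_id = c("HP:0000001", "HP:0000002", "HP:0000002"),
      weight = c(0.9, 0.6, 0.7), stringsAsFactors = FALSE),
    gene_gene = data.frame(
      gene1 = "G1", gene2 = "G5", relation = "biosystem", weight = 0.5,
      stringsAsFactors = FALSE),
    genes = data.frame(
      gene = c("G1", "G2", "G3", "G4", "G5"),
      chrom = "chr1",
      start = c(100, 1100, 2100, 3100, 4100),
      end = c(600, 1600, 2600, 3600, 4600), stringsAsFactors = FALSE))
  class(kb) <- "KnowledgeBase"
  kb
}
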