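#' Per-term raw-score contribution matrix
#'
#' The raw gene score is additive over input HPO terms: the direct part is a
#' weighted bipartite sum over gene-disease and disease-term links, and the
#' single damped propagation round over gene-gene links is linear too. This
#' helper materializes the genes x terms contribution matrix `M` such that
#' `raw(gene, term_set) = sum over t in term_set of M[gene, t]`; it powers
#' both ordinary scoring and the exact subset enumeration, and the
#' equivalence of the two routes is tested.
#'
#' @param kb a `KnowledgeBase`.
#' @param terms HPO ids defining the columns.
#' @param damping propagation weight in [0, 1].
#' @return list: `direct` and `raw` matrices (genes x terms), gene ids as
#'   row names.
#' @keywords internal
score_matrix <- function(kb, terms, damping = 0.5) {
  genes <- sort(unique(c(kb$gene_disease$gene, kb$gene_gene$gene1,
                         kb$gene_gene$gene2, kb$genes$gene)))
  direct <- matrix(0, length(genes), length(terms),
                   dimnames = list(genes, terms))
  dt <- kb$disease_term[kb$disease_term$hpo_id %in% terms, , drop = FALSE]
  if (nrow(dt)) {
    gd <- kb$gene_disease
    m <- merge(gd, dt, by = "disease")
    if (nrow(m)) {
      contrib <- m$weight.x * m$weight.y
      for (i in seq_len(nrow(m)))
        direct[m$gene[i], m$hpo_id[i]] <-
          direct[m$gene[i], m$hpo_id[i]] + contrib[i]
    }
  }
  raw <- direct
  gg <- kb$gene_gene
  if (damping > 0 && nrow(gg)) {
    for (i in seq_len(nrow(gg))) {
      raw[gg$gene1[i], ] <- raw[gg$gene1[i], ] +
        damping * gg$weight[i] * direct[gg$gene2[i], ]
      raw[gg$gene2[i], ] <- raw[gg$gene2[i], ] +
        damping * gg$weight[i] * direct[gg$gene1[i], ]
    }
  }
  list(direct = direct, raw = raw, genes = genes)
}

interval_gene_rows <- function(kb, intervals) {
  lapply(seq_len(nrow(intervals)), function(i) {
    kb$genes$gene[kb$genes$chrom == intervals$chrom[i] &
                  kb$genes$start >= intervals$start[i] &
                  kb$genes$end <= intervals$end[i]]
  })
}

#' Score candidate genes and intervals against an HPO term set
#'
#' The direct score of a gene is the sum over diseases of the gene-disease
#' weight times the summed disease-term weights of the matched input terms;
#' one propagation round then adds `damping` times each neighbour's direct
#' score over the gene-gene links. Genes with positive direct score are seed
#' genes. An interval candidate scores as the maximum over the genes it
#' contains (so long events cannot win by gene count alone; set
#' `interval_agg = "sum"` for the additive variant). Scores are normalized
#' by the maximum raw score across all candidates, so the top candidate gets
#' 1 whenever any raw score is positive, and tiers follow [assign_tier()].
#' Unknown HPO ids are ignored with a warning and listed in the result.
#'
#' @param terms character vector of HPO ids (nonempty).
#' @param candidates list with `genes` (character vector, optional) and
#'   `intervals` (data frame `id`, `chrom`, `start`, `end`, optional).
#' @param kb a `KnowledgeBase`.
#' @param damping propagation weight (0 disables propagation).
#' @param interval_agg `"max"` (default) or `"sum"`.
#' @return a `PrioritizationResult` data frame: `entity`, `type`, `raw`,
#'   `score`, `tier`, `seed_gene`; unknown ids in
#'   `attr(, "unknown_terms")`.
#' @export
score_entities <- function(terms, candidates, kb, damping = 0.5,
                           interval_agg = c("max", "sum")) {
  interval_agg <- match.arg(interval_agg)
  stopifnot(length(terms) >= 1L)
  known <- unique(kb$disease_term$hpo_id)
  unknown <- setdiff(terms, known)
  if (length(unknown))
    warning("ignoring HPO id(s) not in knowledge base: ",
            paste(unknown, collapse = ", "))
  use_terms <- intersect(terms, known)
  cg <- candidates$genes %||% character(0)
  ivl <- candidates$intervals
  n_ivl <- if (is.null(ivl)) 0L else nrow(ivl)
  if (!length(cg) && !n_ivl) stop("no candidates supplied")

  if (length(use_terms)) {
    sm <- score_matrix(kb, use_terms, damping)
    gene_raw <- rowSums(sm$raw[, , drop = FALSE])
    gene_direct <- rowSums(sm$direct[, , drop = FALSE])
  } else {
    genes_all <- sort(unique(c(kb$gene_disease$gene, kb$genes$gene)))
    gene_raw <- gene_direct <- stats::setNames(numeric(length(genes_all)),
                                               genes_all)
  }
  val <- function(g) if (g %in% names(gene_raw)) gene_raw[[g]] else 0
  dval <- function(g) if (g %in% names(gene_direct)) gene_direct[[g]] else 0

  res <- data.frame(entity = character(0), type = character(0),
                    raw = numeric(0), seed_gene = logical(0),
                    stringsAsFactors = FALSE)
  for (g in cg)
    res <- rbind(res, data.frame(entity = g, type = "gene", raw = val(g),
                                 seed_gene = dval(g) > 0))
  if (n_ivl) {
    members <- interval_gene_rows(kb, ivl)
    for (i in seq_len(n_ivl)) {
      vals <- vapply(members[[i]], val, numeric(1))
      agg <- if (!length(vals)) 0
             else if (interval_agg == "max") max(vals) else sum(vals)
      res <- rbind(res, data.frame(
        entity = as.character(ivl$id[i]), type = "interval", raw = agg,
        seed_gene = any(vapply(members[[i]], dval, numeric(1)) > 0)))
    }
  }
  mx <- max(res$raw)
  res$score <- if (mx > 0) res$raw / mx else 0
  res$tier <- assign_tier(res$score)
  res <- res[order(-res$score, res$entity), ]
  rownames(res) <- NULL
  attr(res, "unknown_terms") <- unknown
  class(res) <- c("PrioritizationResult", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign a confidence tier to a normalized score
#'
#' High confidence for scores of at least 0.5, medium for scores in
#' \[0.1, 0.5), low below 0.1; both lower bounds inclusive. Errors on scores
#' outside \[0, 1\].
#'
#' @param score numeric vector of normalized scores.
#' @return character vector, `"high"`, `"medium"` or `"low"`.
#' @export
assign_tier <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 1))
    stop("scores must lie in [0, 1]")
  ifelse(score >= 0.5, "high", ifelse(score >= 0.1, "medium", "low"))
}

#' Per-term importance for a target entity
#'
#' Runs [score_entities()] with each term alone and reports the target's
#' normalized score, sorted descending — how much each phenotype term, by
#' itself, drives the target's prioritization.
#'
#' @param terms HPO ids.
#' @param target entity id (must be among the candidates).
#' @param candidates,kb,damping as in [score_entities()].
#' @return data frame `term`, `score`, sorted by decreasing score.
#' @export
term_importance <- function(terms, target, candidates, kb, damping = 0.5) {
  ids <- c(candidates$genes,
           if (!is.null(candidates$intervals))
             as.character(candidates$intervals$id))
  if (!target %in% ids) stop("target not among candidates: ", target)
  sc <- vapply(terms, function(t) {
    r <- suppressWarnings(score_entities(t, candidates, kb, damping))
    r$score[r$entity == target]
  }, numeric(1))
  out <- data.frame(term = terms, score = unname(sc),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$term), , drop = FALSE]
}

#' Exact binomial coefficient
#'
#' Multiplicative evaluation in which every intermediate value is an exact
#' integer; results are exact up to 2^53 and the function errors beyond
#' rather than silently losing precision.
#'
#' @param n,k non-negative integers, `k <= n`.
#' @return the exact number of k-subsets of n elements.
#' @export
n_combinations <- function(n, k) {
  if (k < 0 || n < 0) stop("n and k must be non-negative")
  if (k > n) stop("k must not exceed n")
  k <- min(k, n - k)
  acc <- 1
  for (i in seq_len(k)) {
    acc <- acc * (n - k + i) / i   # always integer-valued at each step
    if (acc > 2^53) stop("binomial coefficient exceeds exact integer range")
  }
  round(acc)
}

#' Term-subset downsampling robustness analysis
#'
#' For each subset size `k`, scores the target entity on every k-subset of
#' the term set (exhaustively when the number of combinations is within
#' `cap`, otherwise over `cap` distinct subsets sampled without replacement
#' under `seed`) and tallies how often the target lands in each confidence
#' tier. Subset scoring uses the exact per-term contribution matrix, which
#' reproduces [score_entities()] subset by subset.
#'
#' @param terms full HPO term set.
#' @param k_range subset sizes, within `[1, length(terms)]`.
#' @param target entity id whose tier is tallied.
#' @param candidates,kb,damping,interval_agg as in [score_entities()].
#' @param cap maximum number of subsets evaluated per k.
#' @param seed RNG seed for the sampled mode.
#' @return a `CombinationAnalysis` data frame: per k, `n_combinations`
#'   (exact), `n_evaluated`, `mode` ("exhaustive"/"sampled"), counts and
#'   percentages per tier (percentages sum to 100 per row).
#' @export
downsample_analysis <- function(terms, k_range, target, candidates, kb,
                                damping = 0.5, cap = 60000L, seed = 1L,
                                interval_agg = "max") {
  n <- length(terms)
  if (any(k_range < 1L | k_range > n))
    stop("k_range must lie within [1, length(terms)]")
  known <- intersect(terms, unique(kb$disease_term$hpo_id))
  sm <- score_matrix(kb, known, damping)
  M <- matrix(0, nrow(sm$raw), n, dimnames = list(sm$genes, terms))
  M[, known] <- sm$raw

  cg <- candidates$genes %||% character(0)
  ivl <- candidates$intervals
  members <- if (!is.null(ivl)) interval_gene_rows(kb, ivl) else list()
  ivl_ids <- if (!is.null(ivl)) as.character(ivl$id) else character(0)
  all_ids <- c(cg, ivl_ids)
  if (!target %in% all_ids) stop("target not among candidates: ", target)

  gene_row <- function(g) if (g %in% rownames(M)) M[g, , drop = FALSE]
                          else matrix(0, 1, n)

  entity_raw <- function(subset_matrix) {
    # subset_matrix: n x m 0/1 indicators; returns candidates x m raw scores
    out <- matrix(0, length(all_ids), ncol(subset_matrix),
                  dimnames = list(all_ids, NULL))
    for (g in cg) out[g, ] <- gene_row(g) %*% subset_matrix
    for (i in seq_along(ivl_ids)) {
      gs <- members[[i]]
      if (!length(gs)) next
      vals <- do.call(rbind, lapply(gs, function(g) gene_row(g) %*% subset_matrix))
      out[ivl_ids[i], ] <- if (interval_agg == "max")
        apply(vals, 2, max) else colSums(vals)
    }
    out
  }

  rows <- list()
  for (k in sort(unique(k_range))) {
    total <- n_combinations(n, k)
    if (total <= cap) {
      combos <- utils::combn(n, k)
      mode <- "exhaustive"
    } else {
      set.seed(seed + k)
      seen <- new.env(hash = TRUE)
      combos <- matrix(0L, k, 0L)
      while (ncol(combos) < cap) {
        draw <- sort(sample.int(n, k))
        key <- paste(draw, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          combos <- cbind(combos, draw)
        }
      }
      mode <- "sampled"
    }
    ind <- matrix(0, n, ncol(combos))
    ind[cbind(as.vector(combos),
              rep(seq_len(ncol(combos)), each = k))] <- 1
    raws <- entity_raw(ind)
    mx <- apply(raws, 2, max)
    norm <- ifelse(mx > 0, raws[target, ] / mx, 0)
    tiers <- assign_tier(norm)
    cnt <- table(factor(tiers, levels = c("high", "medium", "low")))
    rows[[length(rows) + 1L]] <- data.frame(
      k = k, n_combinations = total, n_evaluated = ncol(combos), mode = mode,
      n_high = as.integer(cnt["high"]), n_medium = as.integer(cnt["medium"]),
      n_low = as.integer(cnt["low"]),
      pct_high = 100 * cnt[["high"]] / ncol(combos),
      pct_medium = 100 * cnt[["medium"]] / ncol(combos),
      pct_low = 100 * cnt[["low"]] / ncol(combos))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("CombinationAnalysis", "data.frame")
  out
}
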