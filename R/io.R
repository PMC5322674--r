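# Genotypes are coded as integer allele-dosage throughout the package:
# 0 = hom_ref, 1 = het, 2 = hom_alt, NA = missing.

GT_CODES <- c(`0/0` = 0L, `0/1` = 1L, `1/0` = 1L, `1/1` = 2L,
              `0|0` = 0L, `0|1` = 1L, `1|0` = 1L, `1|1` = 2L)

IMPACT_LEVELS  <- c("low", "medium", "high")
CLINVAR_LEVELS <- c("pathogenic", "probably_pathogenic", "mixed",
                    "drug_response", "benign", "none")

ANNOTATION_COLS <- c("af_db1", "af_db2", "impact", "is_lof", "cadd",
                     "clinvar", "callers", "alt_coverage", "chi2", "p_adj")

#' Construct a pedigree
#'
#' A pedigree is a data frame with one row per member. Parent links refer to
#' member ids; `NA` means the parent is unknown. Additional logical columns
#' may carry affected status for further phenotype labels (the default label
#' is the `affected` column). The `sequenced` column marks members with
#' genotype data; unsequenced members can still anchor simulation.
#'
#' @param id character vector of unique member ids.
#' @param father,mother parent ids (`NA` for unknown/founder).
#' @param sex "male", "female" or "unknown".
#' @param affected logical affected status for the default phenotype.
#' @param family family id (single value or per-member).
#' @param sequenced logical; whether genotype data exists for the member.
#' @param ... further per-member logical columns (extra phenotype labels).
#' @return a `Pedigree` data frame.
#' @export
Pedigree <- function(id, father = NA_character_, mother = NA_character_,
                     sex = "unknown", affected = FALSE, family = "FAM1",
                     sequenced = TRUE, ...) {
  ped <- data.frame(family = family, id = as.character(id),
                    father = as.character(father), mother = as.character(mother),
                    sex = sex, affected = affected, sequenced = sequenced,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) ped[[nm]] <- extra[[nm]]
  class(ped) <- c("Pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' @rdname Pedigree
#' @param ped object to validate.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  if (nrow(ped) == 0L) stop("pedigree has no members")
  if (anyDuplicated(ped$id)) {
    stop("duplicate pedigree ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  if (!all(ped$sex %in% c("male", "female", "unknown"))) {
    bad <- setdiff(unique(ped$sex), c("male", "female", "unknown"))
    stop("unknown sex code(s): ", paste(bad, collapse = ", "))
  }
  dangling <- setdiff(stats::na.omit(c(ped$father, ped$mother)), ped$id)
  if (length(dangling)) {
    stop("parent id(s) not present in pedigree: ",
         paste(dangling, collapse = ", "))
  }
  # members with a single known parent are legal here (common in real PED
  # files); the simulator additionally requires both-or-neither
  # cycle check via topological ordering
  pedigree_order(ped)
  invisible(ped)
}

# ids ordered so that parents precede children; errors on cycles
pedigree_order <- function(ped) {
  remaining <- ped$id
  placed <- character(0)
  while (length(remaining)) {
    ready <- vapply(remaining, function(i) {
      r <- ped[ped$id == i, ]
      (is.na(r$father) || r$father %in% placed) &&
        (is.na(r$mother) || r$mother %in% placed)
    }, logical(1))
    if (!any(ready)) stop("pedigree contains a cycle involving: ",
                          paste(remaining, collapse = ", "))
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  placed
}

founders <- function(ped) ped$id[is.na(ped$father) & is.na(ped$mother)]

#' Construct a variant set
#'
#' The central genotype container: a site table plus a sites x samples
#' integer dosage matrix (0/1/2, NA = missing). Annotation columns
#' (`af_db1`, `af_db2`, `impact`, `is_lof`, `cadd`, `clinvar`, `callers`,
#' `alt_coverage`, `chi2`, `p_adj`) live on the site table; absent
#' annotations are NA, never silently zero. `callers` is a comma-separated
#' label string (e.g. `"gatk,scalpel"`).
#'
#' @param sites data frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @param geno integer matrix, `nrow(sites)` rows, one named column per sample.
#' @return a `VariantSet` object.
#' @export
variant_set <- function(sites, geno) {
  stopifnot(is.data.frame(sites), is.matrix(geno),
            nrow(sites) == nrow(geno), !is.null(colnames(geno)))
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  for (col in ANNOTATION_COLS) {
    if (is.null(sites[[col]])) {
      sites[[col]] <- if (col %in% c("impact", "clinvar", "callers"))
        NA_character_ else NA_real_
    }
  }
  structure(list(sites = sites, geno = geno), class = "VariantSet")
}

#' @export
print.VariantSet <- function(x, ...) {
  cat(sprintf("VariantSet: %d sites x %d samples on %s\n",
              nrow(x$sites), ncol(x$geno),
              paste(unique(x$sites$chrom), collapse = ",")))
  invisible(x)
}

n_sites <- function(vs) nrow(vs$sites)

geno_of <- function(vs, sample_id) {
  if (!sample_id %in% colnames(vs$geno))
    stop("sample '", sample_id, "' absent from genotype matrix")
  vs$geno[, sample_id]
}

#' Parse a "chrom:start-end" region string
#'
#' Commas in coordinates are tolerated. Coordinates are 1-based inclusive.
#' @param region a string like `"chr15:22,749,401-23,198,800"`, or a list with
#'   `chrom`, `start`, `end` (returned unchanged).
#' @return list with `chrom`, `start`, `end`.
#' @export
parse_region <- function(region) {
  if (is.list(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    return(region[c("chrom", "start", "end")])
  }
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L) stop("cannot parse region string: ", region)
  list(chrom = m[2],
       start = as.numeric(gsub(",", "", m[3])),
       end = as.numeric(gsub(",", "", m[4])))
}

## ---------------------------------------------------------------- PED ----

#' Read / write a PED pedigree file
#'
#' Standard whitespace-delimited 6-column PED: family, id, father, mother,
#' sex (1 = male, 2 = female, 0 = unknown), phenotype (2 = affected,
#' 1 = unaffected, 0 = missing, read as unaffected). `0` parent codes map to
#' unknown.
#'
#' @param path file path.
#' @return `read_ped` returns a [Pedigree]; `write_ped` returns `path`.
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) stop("PED file is empty: ", path)
  f <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(f)
  if (any(ncols < 6L)) {
    stop("PED line(s) with fewer than 6 columns: line ",
         paste(which(ncols < 6L), collapse = ", "))
  }
  m <- do.call(rbind, lapply(f, `[`, 1:6))
  sex_raw <- m[, 5]
  if (!all(sex_raw %in% c("0", "1", "2"))) {
    stop("unknown sex code(s) in PED: ",
         paste(setdiff(unique(sex_raw), c("0", "1", "2")), collapse = ", "))
  }
  Pedigree(id = m[, 2],
           father = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
           mother = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
           sex = c(`0` = "unknown", `1` = "male", `2` = "female")[sex_raw],
           affected = m[, 6] == "2",
           family = m[, 1])
}

#' @rdname read_ped
#' @param ped a [Pedigree].
#' @export
write_ped <- function(ped, path) {
  sex_code <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  lines <- paste(ped$family, ped$id,
                 ifelse(is.na(ped$father), "0", ped$father),
                 ifelse(is.na(ped$mother), "0", ped$mother),
                 sex_code, ifelse(ped$affected, "2", "1"), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------- VCF ----

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), ".", formatC(x, digits = digits, format = "g"))
}

#' Write a minimal VCFv4.2 file
#'
#' Emits GT per sequenced sample and the annotation INFO keys
#' `AF1 AF2 IMPACT LOF CADD CLNSIG CALLERS ALTC CHI2 PADJ`. Missing
#' annotation values are omitted from INFO (not written as 0). Output is
#' byte-deterministic for a given input.
#'
#' @param vs a [variant_set()].
#' @param path output file.
#' @param samples sample ids to emit (default: all columns of the matrix).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, samples = colnames(vs$geno)) {
  s <- vs$sites
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pedwgs",
    sprintf("##contig=<ID=%s>", unique(s$chrom)),
    "##INFO=<ID=AF1,Number=1,Type=Float,Description=\"Population allele frequency, database 1\">",
    "##INFO=<ID=AF2,Number=1,Type=Float,Description=\"Population allele frequency, database 2\">",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Predicted impact class\">",
    "##INFO=<ID=LOF,Number=0,Type=Flag,Description=\"Loss-of-function variant\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"Deleteriousness score\">",
    "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"Clinical significance label\">",
    "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Supporting caller labels\">",
    "##INFO=<ID=ALTC,Number=1,Type=Integer,Description=\"Alternate allele coverage\">",
    "##INFO=<ID=CHI2,Number=1,Type=Float,Description=\"Allele-balance chi-square score\">",
    "##INFO=<ID=PADJ,Number=1,Type=Float,Description=\"Adjusted p-value (pass-through)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  info <- vapply(seq_len(nrow(s)), function(i) {
    kv <- character(0)
    if (!is.na(s$af_db1[i])) kv <- c(kv, paste0("AF1=", fmt_num(s$af_db1[i])))
    if (!is.na(s$af_db2[i])) kv <- c(kv, paste0("AF2=", fmt_num(s$af_db2[i])))
    if (!is.na(s$impact[i])) kv <- c(kv, paste0("IMPACT=", s$impact[i]))
    if (isTRUE(s$is_lof[i] > 0)) kv <- c(kv, "LOF")
    if (!is.na(s$cadd[i])) kv <- c(kv, paste0("CADD=", fmt_num(s$cadd[i])))
    if (!is.na(s$clinvar[i])) kv <- c(kv, paste0("CLNSIG=", s$clinvar[i]))
    if (!is.na(s$callers[i])) kv <- c(kv, paste0("CALLERS=", s$callers[i]))
    if (!is.na(s$alt_coverage[i]))
      kv <- c(kv, paste0("ALTC=", as.integer(s$alt_coverage[i])))
    if (!is.na(s$chi2[i])) kv <- c(kv, paste0("CHI2=", fmt_num(s$chi2[i])))
    if (!is.na(s$p_adj[i])) kv <- c(kv, paste0("PADJ=", fmt_num(s$p_adj[i])))
    if (length(kv)) paste(kv, collapse = ";") else "."
  }, character(1))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[vs$geno[, samples, drop = FALSE] + 1L],
                   nrow = nrow(s))
  gt_str[is.na(gt_str)] <- "./."
  body <- paste(s$chrom, format(s$pos, scientific = FALSE, trim = TRUE), ".",
                s$ref, s$alt, ".", "PASS", info, "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCFv4.2 file
#'
#' Parses GT and the INFO keys written by [write_vcf()]; unknown INFO keys
#' are ignored and missing keys yield NA fields. Multi-allelic records are
#' split into bi-allelic sites with genotype remapping (per split allele,
#' other alternate alleles count as reference); `*` alleles are dropped with
#' a warning.
#'
#' @param path VCF file path.
#' @return a [variant_set()].
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#CHROM\t", lines)
  if (!length(hdr_idx)) stop("malformed VCF (no #CHROM header line): ", path)
  cols <- strsplit(lines[hdr_idx[1]], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[seq_along(lines) > hdr_idx[1]]
  body <- body[nzchar(body)]
  if (!length(body)) stop("VCF has no records: ", path)
  f <- strsplit(body, "\t")
  bad <- which(lengths(f) != length(cols))
  if (length(bad)) {
    stop("malformed VCF record at line ", hdr_idx[1] + bad[1],
         " (expected ", length(cols), " fields)")
  }
  out_sites <- list(); out_geno <- list(); k <- 0L
  for (i in seq_along(f)) {
    r <- f[[i]]
    alts <- strsplit(r[5], ",", fixed = TRUE)[[1]]
    star <- alts == "*"
    if (any(star)) {
      warning("dropping '*' allele at ", r[1], ":", r[2])
    }
    info <- parse_info(r[8])
    gt_raw <- sub(":.*", "", r[-(1:9)])
    al <- strsplit(gt_raw, "[/|]")
    for (j in seq_along(alts)) {
      if (star[j]) next
      dos <- vapply(al, function(a) {
        if (length(a) != 2L || any(a == ".")) return(NA_integer_)
        sum(a == as.character(j))
      }, integer(1))
      k <- k + 1L
      out_sites[[k]] <- data.frame(
        chrom = r[1], pos = as.numeric(r[2]), ref = r[4], alt = alts[j],
        af_db1 = info_num(info, "AF1"), af_db2 = info_num(info, "AF2"),
        impact = info_chr(info, "IMPACT"),
        is_lof = as.numeric("LOF" %in% names(info)),
        cadd = info_num(info, "CADD"), clinvar = info_chr(info, "CLNSIG"),
        callers = info_chr(info, "CALLERS"),
        alt_coverage = info_num(info, "ALTC"), chi2 = info_num(info, "CHI2"),
        p_adj = info_num(info, "PADJ"), stringsAsFactors = FALSE)
      out_geno[[k]] <- dos
    }
  }
  geno <- do.call(rbind, out_geno)
  colnames(geno) <- samples
  variant_set(do.call(rbind, out_sites), geno)
}

parse_info <- function(x) {
  if (x == ".") return(stats::setNames(list(), character(0)))
  kv <- strsplit(x, ";", fixed = TRUE)[[1]]
  eq <- regexpr("=", kv, fixed = TRUE)
  keys <- ifelse(eq > 0, substr(kv, 1, eq - 1), kv)
  vals <- ifelse(eq > 0, substring(kv, eq + 1), NA_character_)
  stats::setNames(as.list(vals), keys)
}
info_num <- function(info, key)
  if (is.null(info[[key]])) NA_real_ else as.numeric(info[[key]])
info_chr <- function(info, key)
  if (is.null(info[[key]])) NA_character_ else info[[key]]

## --------------------------------------------------------- BED / calls ----

#' Read CNV/SV calls from a BED-like file
#'
#' On-disk BED intervals are 0-based half-open; they are converted to the
#' package-wide 1-based inclusive convention on read (`start + 1`, `end`),
#' and back on write. Columns beyond the first three are read from a header
#' line when present (`#chrom start end svtype caller ...`); a plain 3-column
#' BED yields calls of type DEL with caller "unknown".
#'
#' @param path BED or extended-BED file.
#' @return data frame of calls with class `CnvCalls`: `chrom`, `start`,
#'   `end` (1-based inclusive), `svtype`, `caller`, and optional support
#'   columns (`read_support`, `confidence`, `n_markers`,
#'   `max_intermarker_gap`, `segdup_overlap_frac`).
#' @export
read_bed_calls <- function(path) {
  lines <- readLines(path)
  header <- NULL
  if (length(lines) && startsWith(lines[1], "#")) {
    header <- strsplit(sub("^#", "", lines[1]), "[ \t]+")[[1]]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(cnv_calls(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0))))
  }
  f <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(f) < 3L)) stop("BED line with fewer than 3 columns")
  nmax <- max(lengths(f))
  m <- t(vapply(f, function(x) c(x, rep(NA_character_, nmax - length(x))),
                character(nmax)))
  df <- data.frame(chrom = m[, 1], start = as.numeric(m[, 2]) + 1,
                   end = as.numeric(m[, 3]), stringsAsFactors = FALSE)
  extras <- if (!is.null(header)) header[-(1:3)] else character(0)
  for (j in seq_along(extras)) {
    col <- m[, 3 + j]
    df[[extras[j]]] <- if (extras[j] %in% c("svtype", "caller")) col
                       else suppressWarnings(as.numeric(col))
  }
  cnv_calls(df)
}

#' @rdname read_bed_calls
#' @param calls a `CnvCalls` data frame.
#' @export
write_bed_calls <- function(calls, path) {
  extra <- setdiff(names(calls), c("chrom", "start", "end"))
  hdr <- paste0("#", paste(c("chrom", "start", "end", extra), collapse = "\t"))
  num <- function(x) ifelse(is.na(x), ".",
                            format(x, scientific = FALSE, trim = TRUE))
  cols <- c(list(calls$chrom, num(calls$start - 1), num(calls$end)),
            lapply(calls[extra], function(x)
              if (is.numeric(x)) num(x) else ifelse(is.na(x), ".", x)))
  writeLines(c(hdr, do.call(paste, c(cols, sep = "\t"))), path)
  invisible(path)
}

cnv_calls <- function(df) {
  if (is.null(df$svtype)) df$svtype <- rep("DEL", nrow(df))
  if (is.null(df$caller)) df$caller <- rep("unknown", nrow(df))
  if (nrow(df) && any(df$start > df$end)) stop("call with start > end")
  class(df) <- c("CnvCalls", "data.frame")
  df
}

## ------------------------------------------------------------ bedgraph ----

#' Binned depth tracks
#'
#' A `DepthTrack` holds contiguous fixed-width bins starting at base 1 of one
#' chromosome, with per-bin mean read depth. On disk it is a 4-column
#' bedgraph (0-based half-open intervals).
#'
#' @param chrom chromosome label.
#' @param bin_size bin width in bp.
#' @param depth numeric vector of per-bin depths.
#' @return a `DepthTrack`.
#' @export
depth_track <- function(chrom, bin_size, depth) {
  stopifnot(bin_size >= 1, all(depth >= 0, na.rm = TRUE))
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 depth = as.numeric(depth)),
            class = "DepthTrack")
}

#' @export
print.DepthTrack <- function(x, ...) {
  cat(sprintf("DepthTrack: %s, %d bins x %d bp, mean depth %.2f\n",
              x$chrom, length(x$depth), x$bin_size, mean(x$depth)))
  invisible(x)
}

#' @rdname depth_track
#' @param path bedgraph file path.
#' @export
read_depth <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  f <- strsplit(lines, "[ \t]+")
  if (any(lengths(f) != 4L)) stop("bedgraph line without 4 columns")
  m <- do.call(rbind, f)
  start0 <- as.numeric(m[, 2]); end0 <- as.numeric(m[, 3])
  bin <- unique(end0 - start0)
  if (length(bin) != 1L) stop("bedgraph bins are not fixed-width")
  if (any(start0 != (seq_along(start0) - 1) * bin))
    stop("bedgraph bins are not contiguous from position 0")
  depth_track(m[1, 1], bin, as.numeric(m[, 4]))
}

#' @rdname depth_track
#' @param track a `DepthTrack`.
#' @export
write_depth <- function(track, path) {
  n <- length(track$depth)
  start0 <- (seq_len(n) - 1) * track$bin_size
  writeLines(paste(track$chrom,
                   format(start0, scientific = FALSE, trim = TRUE),
                   format(start0 + track$bin_size, scientific = FALSE,
                          trim = TRUE),
                   formatC(track$depth, digits = 6, format = "g"),
                   sep = "\t"), path)
  invisible(path)
}

## ------------------------------------------------------------------ KB ----

#' Read / write a knowledge base directory
#'
#' A knowledge base is four TSV tables in one directory:
#' `gene_disease.tsv` (gene, disease, weight), `disease_term.tsv`
#' (disease, hpo_id, weight), `gene_gene.tsv` (gene1, gene2, relation,
#' weight) and `genes.tsv` (gene, chrom, start, end).
#'
#' @param dir directory containing the tables.
#' @return `read_kb` returns a `KnowledgeBase` list with elements
#'   `gene_disease`, `disease_term`, `gene_gene`, `genes`.
#' @export
read_kb <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f),
                                      stringsAsFactors = FALSE)
  kb <- list(gene_disease = rd("gene_disease.tsv"),
             disease_term = rd("disease_term.tsv"),
             gene_gene = rd("gene_gene.tsv"),
             genes = rd("genes.tsv"))
  class(kb) <- "KnowledgeBase"
  validate_kb(kb)
  kb
}

#' @rdname read_kb
#' @param kb a `KnowledgeBase`.
#' @export
write_kb <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(kb$gene_disease, "gene_disease.tsv")
  wr(kb$disease_term, "disease_term.tsv")
  wr(kb$gene_gene, "gene_gene.tsv")
  wr(kb$genes, "genes.tsv")
  invisible(dir)
}

validate_kb <- function(kb) {
  w <- c(kb$gene_disease$weight, kb$disease_term$weight, kb$gene_gene$weight)
  if (any(w <= 0 | w > 1)) stop("knowledge-base weights must lie in (0, 1]")
  if (nrow(kb$gene_gene) &&
      any(kb$gene_gene$gene1 == kb$gene_gene$gene2))
    stop("knowledge base contains gene-gene self-links")
  invisible(kb)
}
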