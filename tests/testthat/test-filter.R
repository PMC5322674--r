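quad_ped <- function() pedigree_preset("quad")

# helper: single-site variant set over the quad pedigree
quad_vs <- function(fa, mo, c1, c2, chrom = "chr1", ...) {
  make_vs(cbind(father = fa, mother = mo, child = c1, sib = c2),
          chrom = chrom, ...)
}

test_that("trio de novo and recessive assignments follow the definitions", {
  ped <- pedigree_preset("trio")
  vs <- make_vs(cbind(father = c(0L, 0L), mother = c(0L, 1L),
                      child = c(1L, 2L)))
  part <- partition_by_model(vs, ped)
  expect_equal(part$de_novo, 1L)
  expect_false(2L %in% part$de_novo)

  # affected founder hom-alt, unaffected relatives het or hom-ref
  ped2 <- Pedigree(id = c("f2", "m2", "d3"),
                   father = c(NA, NA, "f2"), mother = c(NA, NA, "m2"),
                   sex = c("male", "female", "female"),
                   affected = c(FALSE, TRUE, FALSE))
  vs2 <- make_vs(cbind(f2 = 0L, m2 = 2L, d3 = 1L))
  part2 <- partition_by_model(vs2, ped2)
  expect_equal(part2$autosomal_recessive, 1L)
})

test_that("model partition matches the exhaustive quad-pedigree oracle", {
  ped <- quad_ped()
  combos <- expand.grid(fa = 0:2, mo = 0:2, c1 = 0:2, c2 = 0:2)
  for (on_x in c(FALSE, TRUE)) {
    vs <- make_vs(with(combos, cbind(father = fa, mother = mo,
                                     child = c1, sib = c2)),
                  chrom = if (on_x) "chrX" else "chr1")
    part <- partition_by_model(vs, ped)
    for (i in seq_len(nrow(combos))) {
      expected <- naive_models_quad(
        list(father = combos$fa[i], mother = combos$mo[i],
             child1 = combos$c1[i], child2 = combos$c2[i]), on_x = on_x)
      got <- c("autosomal_dominant", "autosomal_recessive", "de_novo",
               "x_linked_dominant")
      got <- got[vapply(got, function(m) i %in% part[[m]], logical(1))]
      expect_setequal(got, expected)
    }
  }
})

test_that("compound-het pairing respects transmission phasing", {
  ped <- pedigree_preset("trio")
  # sites 1+2: one paternal, one maternal het in the same gene -> trans pair
  # site 3: same gene, also paternal -> cis with site 1, rejected
  # site 4: unphasable (both parents carry) -> unphased flag
  vs <- make_vs(cbind(father = c(1L, 0L, 1L, 1L),
                      mother = c(0L, 1L, 0L, 1L),
                      child = c(1L, 1L, 1L, 1L)))
  gene_map <- rep("GENE_A", 4)
  part <- partition_by_model(vs, ped, gene_map = gene_map)
  ch <- part$compound_het
  trans <- ch[ch$phase == "trans", ]
  expect_true(any(trans$site1 == 1 & trans$site2 == 2))
  expect_false(any(ch$site1 == 1 & ch$site2 == 3))
  expect_true(all(ch$phase[ch$site1 == 4 | ch$site2 == 4] == "unphased"))
  # no gene map -> no compound het evaluation
  part2 <- partition_by_model(vs, ped)
  expect_equal(nrow(part2$compound_het), 0L)
})

test_that("AF filter applies model-specific cut-offs with strict exclusion", {
  vs <- make_vs(matrix(1L, 4, 1, dimnames = list(NULL, "s")),
                af_db1 = c(0.02, 0.05, NA, 0.010),
                af_db2 = c(0.001, 0.05, NA, 0.010))
  dn <- af_filter(1:4, vs, "de_novo")
  expect_setequal(dn$kept, c(3L, 4L))      # 0.02 out, 0.01 boundary kept
  ar <- af_filter(1:4, vs, "autosomal_recessive")
  expect_setequal(ar$kept, 1:4)            # 0.05 boundary kept; NA = novel
  expect_equal(dn$n_kept + dn$n_removed, dn$n_input)
})

test_that("evidence filter enforces the four criteria with criterion 3 disjunctive", {
  vs <- make_vs(matrix(1L, 5, 1, dimnames = list(NULL, "s")),
                callers = c("gatk,freebayes", "gatk", "gatk,freebayes",
                            "gatk,freebayes", "gatk,freebayes"),
                p_adj = c(0.01, 0.01, 0.2, 0.01, 0.01),
                impact = c("low", "high", "high", "low", "medium"),
                is_lof = c(1, 0, 0, 0, 0),
                cadd = c(20, 20, 20, 20, 15.0))
  st <- evidence_filter(1:5, vs)
  expect_true(1L %in% st$kept)                       # LoF rescues low impact
  expect_equal(unname(st$reasons[["2"]]), "caller_concordance")
  expect_equal(unname(st$reasons[["3"]]), "p_adj")
  expect_equal(unname(st$reasons[["4"]]), "impact")
  expect_equal(unname(st$reasons[["5"]]), "cadd")    # 15.0 fails "> 15"
})

test_that("ClinVar rescue is a parallel track over the listed labels", {
  vs <- make_vs(matrix(1L, 5, 1, dimnames = list(NULL, "s")),
                clinvar = c("pathogenic", "benign", "drug_response",
                            "none", "mixed"),
                cadd = c(20, 20, 1, 20, 20))
  rescue <- clinvar_rescue(vs)
  expect_setequal(rescue$site, c(1L, 3L, 5L))
  expect_false(2L %in% rescue$site)
  # recount oracle: exactly the sites with listed labels
  expect_setequal(rescue$site,
                  which(vs$sites$clinvar %in%
                        c("pathogenic", "probably_pathogenic", "mixed",
                          "drug_response")))
})

test_that("the INDEL QC rule is scoped to scalpel and conjunctive as printed", {
  vs <- make_vs(matrix(1L, 4, 1, dimnames = list(NULL, "s")),
                callers = c("scalpel", "scalpel", "gatk", "scalpel"),
                alt_coverage = c(4, 4, 1, 10),
                chi2 = c(11, 5, 50, 50))
  st <- indel_qc_filter(1:4, vs)
  expect_equal(st$removed, 1L)     # both conditions met
  expect_true(2L %in% st$kept)     # low coverage alone survives the AND
  expect_true(3L %in% st$kept)     # non-scalpel untouched
  expect_true(4L %in% st$kept)
  st_or <- indel_qc_filter(1:4, vs, conjunction = FALSE)
  expect_setequal(st_or$removed, c(1L, 2L, 4L))
})

test_that("cascade stages conserve counts and commute on 10,000 variants", {
  ped <- quad_ped()
  spec <- simulation_spec(seed = 99, n_sites = 10000, chrom_length = 5e6,
                          pedigree = ped)
  sim <- generate_pedigree_genotypes(spec)
  vs <- annotate_variants(sim$variants, spec, sim$truth)
  part <- partition_by_model(vs, ped, gene_map = sprintf("G%04d", seq_len(10000) %/% 20L))
  for (model in c("autosomal_dominant", "autosomal_recessive", "de_novo")) {
    tr <- run_filter_cascade(part, vs, model)
    for (st in tr$stages) {
      expect_equal(st$n_kept + st$n_removed, st$n_input)
      expect_equal(length(intersect(st$kept, st$removed)), 0L)
      expect_equal(length(union(st$kept, st$removed)), st$n_input)
    }
    # the trace reconstructs the input set exactly
    removed_all <- unlist(lapply(tr$stages, `[[`, "removed"))
    expect_setequal(c(tr$final_kept, removed_all), tr$input)
  }
  # af and evidence commute
  sites <- part$autosomal_dominant
  a_then_e <- evidence_filter(af_filter(sites, vs, "autosomal_dominant")$kept, vs)$kept
  e_then_a <- af_filter(evidence_filter(sites, vs)$kept, vs, "autosomal_dominant")$kept
  expect_setequal(a_then_e, e_then_a)
})

test_that("a planted pathogenic de novo variant is recovered from 10,000 backgrounds", {
  ped <- quad_ped()
  spec <- simulation_spec(seed = 123, n_sites = 10000, chrom_length = 5e6,
                          pedigree = ped, genotype_error_rate = 0.005)
  sim <- generate_pedigree_genotypes(spec)
  planted <- 5000L
  vs <- annotate_variants(sim$variants, spec, sim$truth,
                          planted_pathogenic = planted)
  vs <- plant_variant(vs, planted,
                      genotypes = c(father = 0L, mother = 0L, child = 1L,
                                    sib = 0L),
                      annotations = list(af_db1 = 0, af_db2 = 0))
  part <- partition_by_model(vs, ped, gene_map = sprintf("G%04d", seq_len(10000) %/% 20L))
  tr <- run_filter_cascade(part, vs, "de_novo")
  expect_true(planted %in% tr$final_kept)
  # independent naive recount of survivors
  g <- vs$geno; s <- vs$sites
  dn <- which(!is.na(g[, "child"]) & g[, "child"] >= 1L &
              !is.na(g[, "father"]) & g[, "father"] == 0L &
              !is.na(g[, "mother"]) & g[, "mother"] == 0L)
  af1 <- ifelse(is.na(s$af_db1), 0, s$af_db1)
  af2 <- ifelse(is.na(s$af_db2), 0, s$af_db2)
  ncall <- lengths(strsplit(ifelse(is.na(s$callers), "", s$callers), ","))
  scalpel_bad <- grepl("scalpel", s$callers) & s$alt_coverage < 5 & s$chi2 > 10.8
  keep <- dn[af1[dn] <= 0.01 & af2[dn] <= 0.01 & !scalpel_bad[dn] &
             ncall[dn] >= 2 & s$p_adj[dn] < 0.05 &
             (s$impact[dn] %in% c("medium", "high") | s$is_lof[dn] > 0) &
             s$cadd[dn] > 15]
  expect_setequal(tr$final_kept, keep)
})

test_that("unknown phenotype labels and affected-less labels error", {
  ped <- quad_ped()
  vs <- quad_vs(0L, 0L, 1L, 0L)
  expect_error(partition_by_model(vs, ped, "nope"), "phenotype")
  ped$affected <- FALSE
  expect_error(partition_by_model(vs, ped), "affected")
})
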