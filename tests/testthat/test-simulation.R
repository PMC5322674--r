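test_that("error-free, deletion-free transmission has zero Mendelian violations", {
  spec <- simulation_spec(seed = 5, n_sites = 2000, chrom_length = 1e6,
                          pedigree = pedigree_preset("three_generation_9"),
                          genotype_error_rate = 0)
  sim <- generate_pedigree_genotypes(spec)
  scan <- mendelian_violation_scan(sim$variants, sim$pedigree)
  expect_true(all(scan$n_violations == 0L))
  expect_true(all(scan$n_eval == 2000L))
})

test_that("same spec and seed reproduce byte-identical outputs", {
  spec <- simulation_spec(seed = 42, n_sites = 300, chrom_length = 1e6,
                          pedigree = pedigree_preset("quad"))
  a <- generate_pedigree_genotypes(spec)
  b <- generate_pedigree_genotypes(spec)
  expect_identical(a$variants$geno, b$variants$geno)
  expect_identical(a$truth$errors, b$truth$errors)
  va <- annotate_variants(a$variants, spec, a$truth)
  vb <- annotate_variants(b$variants, spec, b$truth)
  f1 <- tempfile(); f2 <- tempfile()
  on.exit(unlink(c(f1, f2)))
  write_vcf(va, f1); write_vcf(vb, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("injected genotype errors are logged and drive violations", {
  spec <- simulation_spec(seed = 9, n_sites = 10000, chrom_length = 5e6,
                          genotype_error_rate = 0.01)
  sim <- generate_pedigree_genotypes(spec)
  err <- sim$truth$errors
  # every observed trio violation coincides with a logged error
  scan <- mendelian_violation_scan(sim$variants, sim$pedigree)
  viol_sites <- attr(scan, "violations")[["child"]]
  expect_true(all(viol_sites %in% err$site))
  # number of error-touched sites within binomial 99% interval of the rate
  # implied by 0.01 per genotype across three genotypes
  n_err_sites <- length(unique(err$site))
  p <- 1 - (1 - 0.01)^3
  ci <- qbinom(c(0.005, 0.995), 10000, p)
  expect_gte(n_err_sites, ci[1])
  expect_lte(n_err_sites, ci[2])
  # the log itself is faithful: replaying truth reproduces the matrix
  expect_identical(observed_from_truth(sim), sim$variants$geno)
})

test_that("hemizygous planting matches brute-force haplotype enumeration", {
  spec <- simulation_spec(
    seed = 13, n_sites = 400, chrom_length = 1e6,
    genotype_error_rate = 0,
    deletions = data.frame(start = 250001, end = 750000, carrier = "child",
                           origin = "paternal", de_novo = TRUE))
  sim <- generate_pedigree_genotypes(spec)
  pos <- sim$truth$positions
  inside <- pos >= 250001 & pos <= 750000
  hap_choice <- sim$truth$transmission[["child"]]$mother
  maternal_allele <- sim$truth$haplotypes[["mother"]][
    cbind(seq_along(pos), hap_choice)]
  expected_inside <- 2L * maternal_allele[inside]
  expect_identical(unname(sim$variants$geno[inside, "child"]),
                   expected_inside)
  # outside the segment the ordinary diploid sum stands
  diploid <- sim$truth$haplotypes[["child"]][, 1] +
    sim$truth$haplotypes[["child"]][, 2]
  expect_identical(unname(sim$variants$geno[!inside, "child"]),
                   diploid[!inside])
  # father hom-alt with a ref maternal allele forces an observed hom-ref
  # proband: a Mendelian violation
  fg <- sim$variants$geno[, "father"]
  forced <- inside & fg == 2L & maternal_allele == 0L
  if (any(forced))
    expect_true(all(sim$variants$geno[forced, "child"] == 0L))
})

test_that("planting enumerates correctly over all maternal haplotype configurations", {
  # hand-built truth: every (hap1, hap2, transmitted) combination
  cfg <- expand.grid(h1 = 0:1, h2 = 0:1, tr = 1:2)
  n <- nrow(cfg)
  ped <- pedigree_preset("trio")
  vs <- make_vs(cbind(father = rep(1L, n), mother = cfg$h1 + cfg$h2,
                      child = rep(1L, n)))
  truth <- list(
    haplotypes = list(mother = cbind(cfg$h1, cfg$h2)),
    transmission = list(child = list(father = rep(1L, n), mother = cfg$tr)))
  plan <- data.frame(start = 1, end = max(vs$sites$pos), carrier = "child",
                     origin = "paternal", de_novo = TRUE, copies = 1L)
  out <- plant_deletions(vs, ped, plan, truth)
  expected <- 2L * ifelse(cfg$tr == 1L, cfg$h1, cfg$h2)
  expect_identical(unname(out$variants$geno[, "child"]), as.integer(expected))
})

test_that("planting a parental-origin deletion in a founder errors", {
  spec <- simulation_spec(seed = 1, n_sites = 50, chrom_length = 1e5)
  sim <- generate_pedigree_genotypes(spec)
  plan <- data.frame(start = 1, end = 1e5, carrier = "father",
                     origin = "paternal", de_novo = TRUE)
  expect_error(plant_deletions(sim$variants, sim$pedigree, plan, sim$truth),
               "founder")
})

test_that("depth simulation follows the copy-number scaled Poisson law", {
  del <- data.frame(start = 200001, end = 400000, carrier = "child",
                    origin = "paternal", de_novo = TRUE, copies = 1L)
  spec <- simulation_spec(seed = 21, n_sites = 10, chrom_length = 1e6,
                          mean_coverage = 40, bin_size = 100,
                          deletions = del)
  tr <- simulate_depth(spec)
  expect_length(tr$depth, 10000L)
  in_del <- 2001:4000   # 2,000 full bins inside the deletion
  se <- sqrt(20 / length(in_del))
  expect_lt(abs(mean(tr$depth[in_del]) - 20), 3 * se)
  out_del <- c(1:2000, 4001:10000)
  se2 <- sqrt(40 / length(out_del))
  expect_lt(abs(mean(tr$depth[out_del]) - 40), 3 * se2)
  # homozygous deletion: all in-region bins exactly zero
  del0 <- transform(del, copies = 0L)
  tr0 <- simulate_depth(spec, deletions = del0)
  expect_true(all(tr0$depth[in_del] == 0))
  # diploid everywhere
  trd <- simulate_depth(spec, deletions = NULL)
  expect_lt(abs(mean(trd$depth) - 40), 3 * sqrt(40 / 10000))
})

test_that("annotations are complete, correlated with truth AF, and honor planting", {
  spec <- simulation_spec(seed = 31, n_sites = 10000, chrom_length = 5e6)
  sim <- generate_pedigree_genotypes(spec)
  vs <- annotate_variants(sim$variants, spec, sim$truth,
                          planted_pathogenic = c(10L, 20L))
  s <- vs$sites
  for (col in c("af_db1", "af_db2", "impact", "is_lof", "cadd", "clinvar",
                "callers", "alt_coverage", "chi2", "p_adj"))
    expect_false(any(is.na(s[[col]])), info = col)
  expect_gt(cor(s$af_db1, sim$truth$af, method = "spearman"), 0.9)
  expect_gt(cor(s$af_db2, sim$truth$af, method = "spearman"), 0.9)
  expect_true(all(s$clinvar[c(10, 20)] == "pathogenic"))
  expect_true(all(s$cadd[c(10, 20)] > 15))
  ncallers <- lengths(strsplit(s$callers, ","))
  expect_true(all(ncallers >= 1 & ncallers <= 3))
})

test_that("knowledge-base generation plants the disease cluster deterministically", {
  kb1 <- generate_knowledge_base(seed = 8)
  kb2 <- generate_knowledge_base(seed = 8)
  expect_identical(kb1$gene_disease, kb2$gene_disease)
  expect_identical(kb1$genes, kb2$genes)
  planted <- kb1$truth
  links <- kb1$gene_disease[kb1$gene_disease$disease == planted$disease, ]
  expect_setequal(links$gene, planted$genes)
  expect_true(all(links$weight > 0))
  # planted genes sit inside the designated region, background genes outside
  g <- kb1$genes
  in_reg <- g$start >= planted$region[1] & g$end <= planted$region[2]
  expect_setequal(g$gene[in_reg], planted$genes)
})

test_that("invalid specs are rejected", {
  expect_error(simulation_spec(genotype_error_rate = 0.6), "error_rate")
  expect_error(simulation_spec(
    deletions = data.frame(start = c(1, 50), end = c(100, 200),
                           carrier = "child", origin = "paternal"),
    pedigree = pedigree_preset("trio")), "overlap")
  ped <- pedigree_preset("trio")
  ped$mother[3] <- NA
  spec <- simulation_spec(pedigree = ped)
  expect_error(generate_pedigree_genotypes(spec), "both parents")
})
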