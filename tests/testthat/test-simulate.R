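test_that("identical config and seed give identical datasets", {
  cfg <- small_sim_config(seed = 99)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$vs$geno, b$vs$geno)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$tpm, b$tpm)
  c2 <- generate_dataset(small_sim_config(seed = 100))
  expect_false(identical(a$vs$geno, c2$vs$geno))
})

test_that("no mutation and no background gives an all-reference collection", {
  cfg <- sim_config(n_samples = 10, n_del_sites = 50, n_fixed = 0,
                    n_decoy = 0, mu_storage = 0, mu_regen = 0,
                    background = list(p_zero = 1, beta = c(0.5, 9), f = 0.95),
                    seed = 5)
  sched <- list(y_acq = 30, regen_years = c(10, 20))
  out <- simulate_accession(cfg, sched, rep(0L, 50))
  expect_true(all(out$genotype == 0L))
  expect_true(all(out$trajectory$n_het == 0))
  expect_true(all(out$trajectory$n_hom == 0))
})

test_that("full purging removes segregating homozygotes but cannot touch fixed load", {
  cfg <- sim_config(n_samples = 1, n_del_sites = 200, n_decoy = 0,
                    n_fixed = 0, mu_storage = 0, mu_regen = 0,
                    s = 1, h = 0, seed = 8)
  set.seed(8)
  for (i in 1:20) {
    # every site heterozygous going into a regeneration under s = 1:
    # selfed homozygotes are lethal, so none can be assayed afterwards
    out <- simulate_accession(cfg, list(y_acq = 1, regen_years = 1),
                              rep(1L, 200))
    expect_equal(sum(out$genotype == 2L), 0)
    expect_true(all(out$genotype %in% c(0L, 1L)))
  }
  # alleles already fixed within the accession segregate no viability
  # variance in a selfed family, so even s = 1 cannot purge them
  out2 <- simulate_accession(cfg, list(y_acq = 2, regen_years = 2),
                             rep(2L, 200))
  expect_true(all(out2$genotype == 2L))
})

test_that("genotype states stay in {0,1,2} along the whole trajectory", {
  cfg <- small_sim_config(seed = 12)
  sim <- generate_dataset(cfg)
  expect_true(all(sim$vs$geno %in% 0:2))
  tr <- sim$truth$trajectories
  expect_true(all(tr$n_het >= 0 & tr$n_hom >= 0 &
                    tr$n_het + tr$n_hom <= cfg$n_del_sites))
})

test_that("neutral selfing halves the expected heterozygous count", {
  cfg <- sim_config(n_samples = 1, n_del_sites = 60, n_decoy = 0,
                    n_fixed = 0, mu_storage = 0, mu_regen = 0, s = 0,
                    seed = 3)
  set.seed(33)
  reps <- 4000
  het_after <- numeric(reps)
  init <- rep(1L, 60)
  for (i in seq_len(reps)) {
    out <- simulate_accession(cfg, list(y_acq = 1, regen_years = 1), init)
    het_after[i] <- sum(out$genotype == 1L)
  }
  # selfing expectation: E(het') = het / 2; MC error ~ sqrt(15/4000) ~ 0.06
  expect_equal(mean(het_after), 30, tolerance = 0.02)
})

test_that("pooled mode keeps a plant matrix and respects the rejection cap", {
  cfg <- sim_config(n_samples = 1, n_del_sites = 30, n_decoy = 0,
                    n_fixed = 0, mu_storage = 0, mu_regen = 0, s = 0.5,
                    h = 0.1, n_regen = 8, mode = "pooled", seed = 2)
  set.seed(2)
  init <- matrix(sample(0:2, 30 * 8, TRUE, prob = c(.7, .2, .1)), 30, 8)
  out <- simulate_accession(cfg, list(y_acq = 5, regen_years = c(2, 4)), init)
  expect_equal(dim(out$plants), c(30, 8))
  expect_true(all(out$plants %in% 0:2))
  expect_true(all(out$genotype %in% 0:2))

  # an impossible family (every site a lethal homozygote segregating) trips
  # the cap error rather than silently truncating
  cfg_bad <- sim_config(n_samples = 1, n_del_sites = 400, n_decoy = 0,
                        n_fixed = 0, s = 1, h = 0.99, n_regen = 2,
                        mode = "pooled", reject_cap = 50, seed = 2)
  init_bad <- matrix(1L, 400, 2)
  expect_error(
    simulate_accession(cfg_bad, list(y_acq = 1, regen_years = 1), init_bad),
    "survival probability")
})

test_that("emitted dataset is internally consistent with its truth record", {
  sim <- generate_dataset(small_sim_config(seed = 21))
  # metadata invariants hold
  m <- sim$metadata
  expect_true(all(m$y_last <= m$y_acq))
  expect_true(all(m$y_last[m$r_cycles == 0] == m$y_acq[m$r_cycles == 0]))
  expect_true(all(m$rin >= 1 & m$rin <= 10))
  # pipeline burdens from the emitted genotypes equal the truth counts
  dset <- classify_deleterious(sim$annotation)
  expect_setequal(dset$key, sim$truth$del_keys)
  b <- compute_burdens(sim$vs, dset)
  expect_equal(b$n_het, unname(sim$truth$n_het))
  expect_equal(b$n_hom, unname(sim$truth$n_hom))
  expect_equal(b$L[1], sim$truth$L)
  # trajectories end at the assayed genotype
  tr <- sim$truth$trajectories
  last <- tr[!duplicated(tr$sample_id, fromLast = TRUE), ]
  last <- last[match(b$sample_id, last$sample_id), ]
  expect_equal(b$n_het, last$n_het)
  expect_equal(b$n_hom, last$n_hom)
})

test_that("file round trip: written dataset reanalyzes to the same burdens", {
  sim <- generate_dataset(small_sim_config(seed = 77))
  dir <- tempfile()
  write_sim_output(sim, dir)
  vs <- filter_variants(read_vcf(file.path(dir, "genotypes.vcf.gz")))
  expect_equal(vs$sites$key, sim$vs$sites$key)
  expect_equal(unname(vs$geno), unname(sim$vs$geno))
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  dset <- classify_deleterious(ann)
  b_file <- compute_burdens(vs, dset)
  b_mem <- compute_burdens(sim$vs, classify_deleterious(sim$annotation))
  expect_equal(b_file$b_tot, b_mem$b_tot)
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(meta$y_acq, sim$metadata$y_acq)
})

test_that("mutation-free inbred collections show burden slopes only at the false-positive rate", {
  null_sig <- 0L
  het_ps <- numeric(12)
  for (i in 1:12) {
    sim <- generate_dataset(small_sim_config(
      mu_storage = 0, mu_regen = 0,
      background = list(p_zero = 0.30, beta = c(0.5, 9), f = 1),
      seed = 5200 + i))
    rp <- recover_parameters(sim)
    null_sig <- null_sig + (rp$p_value[2] < 0.05) + (rp$p_value[3] < 0.05)
    het_ps[i] <- rp$p_value[1]
  }
  # constant zero heterozygous burden carries no association at all
  expect_true(all(het_ps == 1))
  # 24 null slope tests at alpha = 0.05: allow up to 4 hits (P ~ 0.007)
  expect_lte(null_sig, 4)
})

test_that("empty deleterious classification propagates the documented error", {
  sim <- generate_dataset(small_sim_config(seed = 31))
  none <- classify_deleterious(sim$annotation, sift_max = 0)
  expect_equal(nrow(none), 0)
  expect_error(compute_burdens(sim$vs, none), "no deleterious loci")
})
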