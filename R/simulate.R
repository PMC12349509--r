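# Forward-in-time simulator of selfing germplasm under cold-storage mutation,
# regeneration (selfing transmission + viability selection = purging), and
# single-seed-descent drift. Emits genotype/annotation/metadata/TPM fixtures
# with known truth so the whole pipeline is testable by parameter recovery.

#' Simulator configuration
#'
#' Builds and validates the generative parameters of the conservation
#' simulator. The defaults describe a 190-accession, 588-deleterious-site
#' selfing collection conserved over a 1972-2004 acquisition window with up
#' to 10 regeneration cycles and 4-25 years since the last regeneration,
#' under strong purging (selection coefficient `s` against the homozygous
#' deleterious genotype close to 1, small dominance `h`). Both mutation rates
#' are deliberately inflated far above per-generation point-mutation rates so
#' that desk-scale collections carry a measurable signal; they are knobs, not
#' estimates.
#'
#' @param n_samples Number of accessions.
#' @param n_del_sites Number of potential deleterious sites (includes
#'   `n_fixed` sites fixed for the deleterious allele in every accession).
#' @param n_fixed Count of collection-wide fixed deleterious sites.
#' @param n_decoy Number of non-deleterious decoy SNPs emitted alongside.
#' @param mu_storage Per-allele, per-year deleterious mutation probability in
#'   cold storage.
#' @param mu_regen Per-allele deleterious mutation probability at a
#'   regeneration event (the sexual generation).
#' @param s Selection coefficient against the homozygous deleterious
#'   genotype at regeneration; heterozygote fitness is `1 - h * s`.
#' @param h Dominance coefficient.
#' @param n_regen Plants grown per regeneration (pooled mode; the
#'   single-seed-descent marginal does not depend on it).
#' @param mode `"single_seed"` (default) or `"pooled"`.
#' @param reject_cap Rejection-sampling cap per seed slot in pooled mode.
#' @param background List: standing deleterious-allele frequency model per
#'   site (`p_zero` mass at 0, `beta` shape parameters otherwise) and the
#'   accession inbreeding coefficient `f` used to spread a frequency into
#'   genotypes.
#' @param decoy List: decoy-site frequency model (`beta`), fraction of
#'   invariant-heterozygous decoys (`p_invariant_het`), fraction of decoy
#'   missense calls that are low-confidence SIFT-deleterious
#'   (`p_low_confidence`), and fraction of decoys lacking an RS score
#'   (`p_rs_missing`).
#' @param annotation_model List: `severity_probs` (weak/mild/high mixture for
#'   deleterious-site RS scores) and `sift_del_max` (upper SIFT bound of the
#'   deleterious sites).
#' @param expression_model List of coefficients linking expressed gene count,
#'   mean TPM and RIN to total burden and the conservation covariates, plus
#'   noise scales and the expression panel sizes (`n_genes` panel,
#'   `n_core` genes expressed in every sample).
#' @param reference_year Assay year; elapsed covariates are relative to it.
#' @param acq_years Calendar acquisition-year range.
#' @param y_last_range Range of years since the last regeneration.
#' @param r_max Maximum regeneration cycles.
#' @param r_per_year,r_noise_sd Regeneration cycles rise with accession age
#'   at `r_per_year` cycles/year (plus Gaussian noise, clamped to
#'   `[0, r_max]`) -- older accessions have been regenerated more.
#' @param n_gene_pool Gene-id pool size for annotation.
#' @param countries Character vector of origin labels.
#' @param country_weights Sampling weights (first entry dominant).
#' @param seed RNG seed used by [generate_dataset()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 190,
                       n_del_sites = 588,
                       n_fixed = 1,
                       n_decoy = 1200,
                       mu_storage = 2e-4,
                       mu_regen = 5e-3,
                       s = 0.98,
                       h = 0.05,
                       n_regen = 30,
                       mode = c("single_seed", "pooled"),
                       reject_cap = 1e4,
                       background = list(p_zero = 0.30,
                                         beta = c(0.5, 9),
                                         f = 0.95),
                       decoy = list(beta = c(0.25, 2.5),
                                    p_invariant_het = 0.023,
                                    p_low_confidence = 0.06,
                                    p_rs_missing = 0.40),
                       annotation_model = list(
                         severity_probs = c(weak = 0.077, mild = 0.811,
                                            high = 0.112),
                         sift_del_max = 0.05),
                       expression_model = list(
                         n_genes = 175, n_core = 119,
                         rin_intercept = 8.8, rin_y_last = -0.077,
                         rin_b_tot = -8, rin_sd = 0.25,
                         gc_intercept = 155, gc_b_tot = -350, gc_rin = 1.5,
                         gc_y_acq = 0.15, gc_sd = 4,
                         tpm_intercept = 13.2, tpm_b_tot = 60,
                         tpm_y_last = 0.08, tpm_gc = -0.08, tpm_sd = 1.2,
                         gene_log_mean = log(10), gene_log_sd = 0.8,
                         tpm_gene_sd = 0.4),
                       reference_year = 2022,
                       acq_years = c(1972, 2004),
                       y_last_range = c(4, 25),
                       r_max = 10,
                       r_per_year = 1 / 3.2,
                       r_noise_sd = 1.2,
                       n_gene_pool = 450,
                       countries = c("Canada", "China", "Poland", "Russia",
                                     "South Korea", "Sweden", "Hungary",
                                     "Switzerland", "Yugoslavia", "Lithuania",
                                     "USA", "Japan", "Ukraine", "Germany",
                                     "France", "Romania", "Czechia",
                                     "Slovakia", "Belarus", "Netherlands",
                                     "Italy"),
                       country_weights = NULL,
                       seed = 1) {
  mode <- match.arg(mode)
  if (is.null(country_weights))
    country_weights <- c(8, rep(1.5, 7), rep(0.6, length(countries) - 8))
  cfg <- list(
    n_samples = n_samples, n_del_sites = n_del_sites, n_fixed = n_fixed,
    n_decoy = n_decoy, mu_storage = mu_storage, mu_regen = mu_regen,
    s = s, h = h, n_regen = n_regen, mode = mode, reject_cap = reject_cap,
    background = background, decoy = decoy,
    annotation_model = annotation_model, expression_model = expression_model,
    reference_year = reference_year, acq_years = acq_years,
    y_last_range = y_last_range, r_max = r_max, r_per_year = r_per_year,
    r_noise_sd = r_noise_sd, n_gene_pool = n_gene_pool,
    countries = countries, country_weights = country_weights, seed = seed
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      n_samples >= 1, n_del_sites >= 1, n_fixed >= 0,
      n_fixed <= n_del_sites, n_decoy >= 0,
      mu_storage >= 0, mu_storage <= 1, mu_regen >= 0, mu_regen <= 1,
      s >= 0, s <= 1, h >= 0, h * s <= s, n_regen >= 1,
      y_last_range[1] >= 0, r_max >= 0
    )
  })
  structure(cfg, class = c("sim_config", "list"))
}

# Offspring genotype distribution per site under selfing transmission,
# gamete mutation at rate mu, and (optionally) viability weighting relative
# to the within-family baseline. Returns an L x 3 matrix of probabilities.
selfing_offspring_probs <- function(parent, s, h, mu, select = TRUE) {
  L <- length(parent)
  p <- matrix(0, L, 3)
  m0 <- c((1 - mu)^2, 2 * mu * (1 - mu), mu^2)  # mutation from state 0
  i0 <- parent == 0L
  p[i0, 1] <- m0[1]; p[i0, 2] <- m0[2]; p[i0, 3] <- m0[3]
  i1 <- parent == 1L
  p[i1, 1] <- 0.25 * m0[1]
  p[i1, 2] <- 0.25 * m0[2] + 0.5 * (1 - mu)
  p[i1, 3] <- 0.25 * m0[3] + 0.5 * mu + 0.25
  i2 <- parent == 2L
  p[i2, 3] <- 1
  if (select) {
    w <- c(1, 1 - h * s, 1 - s)
    pw <- sweep(p, 2, w, `*`)
    tot <- rowSums(pw)
    # a site whose only reachable state has zero viability weight (e.g. a
    # lethal fixed homozygote) carries no within-family selection
    # differential: transmission there is unweighted
    deg <- tot <= 0
    if (any(deg)) {
      pw[deg, ] <- p[deg, , drop = FALSE]
      tot[deg] <- 1
    }
    p <- pw / tot
  }
  p
}

sample_states <- function(p) {
  u <- stats::runif(nrow(p))
  (u > p[, 1]) + (u > p[, 1] + p[, 2])
}

# One year of cold-storage mutation: each remaining reference allele copy
# independently mutates to the deleterious state with probability mu.
storage_mutate <- function(g, mu) {
  if (mu <= 0) return(g)
  idx <- which(g < 2L)
  if (length(idx))
    g[idx] <- g[idx] + stats::rbinom(length(idx), 2L - g[idx], mu)
  g
}

#' Simulate one accession through storage and regeneration
#'
#' Runs an accession forward from acquisition to the assay year. Each storage
#' year, every remaining reference allele copy mutates to the deleterious
#' state with probability `mu_storage` (irreversible). At each scheduled
#' regeneration the stored genotype is selfed: offspring follow Mendelian
#' selfing transmission with gamete mutation at `mu_regen`, and viability
#' selection weights genotypes `1 : 1-hs : 1-s` relative to the within-family
#' baseline (sites fixed in the parent segregate no viability variance within
#' a selfed family). In `single_seed` mode the next stored genotype is one
#' surviving seed, drawn site-wise from the exact survivor distribution; in
#' `pooled` mode `n_regen` plants are maintained and each seed slot is
#' filled by rejection sampling (cap `reject_cap`) from a uniformly chosen
#' parent plant.
#'
#' @param cfg A [sim_config()].
#' @param schedule List with `y_acq` (years from acquisition to assay) and
#'   `regen_years` (sorted years-after-acquisition of regeneration events).
#' @param init Integer initial genotype vector (0/1/2) of length
#'   `cfg$n_del_sites` (single-seed), or an L x `n_regen` matrix (pooled).
#' @return List with `genotype` (assay-year genotype vector; pooled mode
#'   returns the matrix plus a `genotype` column drawn for assay),
#'   `trajectory` (data.frame year, event, n_het, n_hom).
#' @export
simulate_accession <- function(cfg, schedule, init) {
  stopifnot(inherits(cfg, "sim_config"))
  y_acq <- schedule$y_acq
  regen <- schedule$regen_years
  stopifnot(all(regen >= 1), all(regen <= y_acq), !is.unsorted(regen))
  pooled <- cfg$mode == "pooled"
  g <- if (pooled) {
    if (is.matrix(init)) init else matrix(init, length(init), cfg$n_regen)
  } else as.integer(init)
  traj <- vector("list", y_acq + 1)
  snap <- function(x) {
    if (is.matrix(x)) c(mean(colSums(x == 1L)), mean(colSums(x == 2L)))
    else c(sum(x == 1L), sum(x == 2L))
  }
  rec <- snap(g)
  traj[[1]] <- data.frame(year = 0, event = "init",
                          n_het = rec[1], n_hom = rec[2])
  if (y_acq > 0) for (yr in seq_len(y_acq)) {
    g <- if (pooled) {
      matrix(storage_mutate(as.integer(g), cfg$mu_storage), nrow(g), ncol(g))
    } else storage_mutate(g, cfg$mu_storage)
    ev <- "storage"
    if (yr %in% regen) {
      g <- if (pooled) regenerate_pooled(g, cfg) else regenerate_single(g, cfg)
      ev <- "regeneration"
    }
    rec <- snap(g)
    traj[[yr + 1]] <- data.frame(year = yr, event = ev,
                                 n_het = rec[1], n_hom = rec[2])
  }
  genotype <- if (pooled) g[, sample.int(ncol(g), 1)] else g
  list(genotype = as.integer(genotype),
       plants = if (pooled) g else NULL,
       trajectory = do.call(rbind, traj))
}

regenerate_single <- function(g, cfg) {
  p <- selfing_offspring_probs(g, cfg$s, cfg$h, cfg$mu_regen, select = TRUE)
  as.integer(sample_states(p))
}

regenerate_pooled <- function(plants, cfg) {
  L <- nrow(plants); k <- ncol(plants)
  out <- matrix(0L, L, k)
  w3 <- c(1, 1 - cfg$h * cfg$s, 1 - cfg$s)
  for (slot in seq_len(k)) {
    tries <- 0
    repeat {
      tries <- tries + 1
      if (tries > cfg$reject_cap)
        stop("survival probability numerically 0 after ", cfg$reject_cap,
             " tries; reduce s or the site count")
      parent <- plants[, sample.int(k, 1)]
      p <- selfing_offspring_probs(parent, cfg$s, cfg$h, cfg$mu_regen,
                                   select = FALSE)
      seed <- sample_states(p)
      varying <- parent != 2L
      w <- prod(w3[seed[varying] + 1L])
      if (stats::runif(1) < w) break
    }
    out[, slot] <- seed
  }
  out
}

draw_schedules <- function(cfg) {
  n <- cfg$n_samples
  y_acq <- cfg$reference_year -
    sample(seq(cfg$acq_years[1], cfg$acq_years[2]), n, replace = TRUE)
  min_acq <- cfg$reference_year - cfg$acq_years[2]
  r <- pmin(pmax(round((y_acq - min_acq) * cfg$r_per_year +
                         stats::rnorm(n, 0, cfg$r_noise_sd)), 0), cfg$r_max)
  y_last <- integer(n)
  schedules <- vector("list", n)
  for (i in seq_len(n)) {
    if (r[i] == 0) {
      y_last[i] <- y_acq[i]
      schedules[[i]] <- list(y_acq = y_acq[i], regen_years = integer(0))
    } else {
      hi <- min(cfg$y_last_range[2], y_acq[i] - r[i])
      y_last[i] <- if (hi <= cfg$y_last_range[1]) hi
                   else sample(seq(cfg$y_last_range[1], hi), 1)
      t_last <- y_acq[i] - y_last[i]
      earlier <- if (r[i] > 1)
        sort(sample(seq_len(t_last - 1), r[i] - 1)) else integer(0)
      schedules[[i]] <- list(y_acq = y_acq[i],
                             regen_years = c(earlier, t_last))
    }
  }
  list(y_acq = y_acq, y_last = y_last, r = as.integer(r),
       schedules = schedules)
}

draw_background_geno <- function(q, n, f) {
  # spread a per-site allele frequency into inbred-accession genotypes
  L <- length(q)
  p_hom <- q^2 + f * q * (1 - q)
  p_het <- (1 - f) * 2 * q * (1 - q)
  u <- matrix(stats::runif(L * n), L, n)
  m <- (u < p_hom) + (u < p_hom + p_het)  # 2 with prob p_hom, 1 with p_het
  storage.mode(m) <- "integer"
  m
}

#' Generate a complete synthetic dataset
#'
#' Draws per-accession conservation covariates (acquisition age, regeneration
#' cycles rising with age, years since last regeneration), simulates every
#' accession's deleterious-site genotype forward in time, adds neutral decoy
#' SNPs (inbred-accession genotypes from an L-shaped frequency model plus a
#' small invariant-heterozygous fraction), and emits a SIFT/RS annotation
#' table, accession metadata with RIN, and a TPM expression matrix whose
#' structure is tied to true burden and the covariates. All randomness flows
#' from `cfg$seed`; identical configs give identical outputs.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_output`: `vs` (complete `variant_set` with
#'   site QUAL and per-call DP), `annotation` (`annotation_table`),
#'   `metadata` (`accession_metadata`), `tpm` (genes x samples matrix),
#'   `truth` (realized per-accession counts, trajectories, per-site
#'   frequencies, covariates), and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  sample_ids <- sprintf("ACC%03d", seq_len(n))

  cov <- draw_schedules(cfg)

  # --- deleterious sites: standing variation + forward simulation ---
  L <- cfg$n_del_sites
  q <- numeric(L)
  if (cfg$n_fixed > 0) q[seq_len(cfg$n_fixed)] <- 1
  free <- setdiff(seq_len(L), seq_len(cfg$n_fixed))
  nz <- stats::runif(length(free)) >= cfg$background$p_zero
  q[free[nz]] <- stats::rbeta(sum(nz), cfg$background$beta[1],
                              cfg$background$beta[2])
  init <- draw_background_geno(q, n, cfg$background$f)
  init[seq_len(cfg$n_fixed), ] <- 2L

  del_geno <- matrix(0L, L, n)
  traj <- vector("list", n)
  for (i in seq_len(n)) {
    acc <- simulate_accession(cfg, cov$schedules[[i]], init[, i])
    del_geno[, i] <- acc$genotype
    tr <- acc$trajectory
    tr$sample_id <- sample_ids[i]
    traj[[i]] <- tr
  }

  # --- decoy sites: neutral inbred genotypes, L-shaped spectrum ---
  nd <- cfg$n_decoy
  inv_het <- stats::runif(nd) < cfg$decoy$p_invariant_het
  qd <- stats::rbeta(nd, cfg$decoy$beta[1], cfg$decoy$beta[2])
  decoy_geno <- draw_background_geno(qd, n, cfg$background$f)
  decoy_geno[inv_het, ] <- 1L

  # drop monomorphic (all hom-ref) sites: they are not SNPs
  del_keep <- rowSums(del_geno) > 0
  decoy_keep <- rowSums(decoy_geno) > 0
  del_geno <- del_geno[del_keep, , drop = FALSE]
  decoy_geno <- decoy_geno[decoy_keep, , drop = FALSE]
  L_real <- nrow(del_geno); nd_real <- nrow(decoy_geno)

  # --- coordinates, alleles, site qualities ---
  n_sites <- L_real + nd_real
  chroms <- sprintf("Chr%02d", 1:20)
  site_chrom <- sample(chroms, n_sites, replace = TRUE)
  site_pos <- integer(n_sites)
  for (ch in chroms) {
    idx <- which(site_chrom == ch)
    site_pos[idx] <- sort(sample.int(5e7, length(idx)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  is_del <- c(rep(TRUE, L_real), rep(FALSE, nd_real))
  ord <- order(site_chrom, site_pos)
  geno <- rbind(del_geno, decoy_geno)[ord, , drop = FALSE]
  is_del <- is_del[ord]
  sites <- data.frame(
    chrom = site_chrom[ord], pos = site_pos[ord],
    ref = ref[ord], alt = alt[ord],
    qual = round(stats::runif(n_sites, 60, 600), 1),
    key = site_key(site_chrom[ord], site_pos[ord], ref[ord], alt[ord]),
    stringsAsFactors = FALSE
  )
  dp <- matrix(10L + stats::rpois(n_sites * n, 25), n_sites, n)
  vs <- new_variant_set(sites, geno, sample_ids, dp = dp)

  # --- annotation ---
  ann <- simulate_annotation(cfg, sites, is_del)

  # --- burden truth over realized deleterious sites ---
  del_keys <- sites$key[is_del]
  gdel <- geno[is_del, , drop = FALSE]
  n_het <- as.integer(colSums(gdel == 1L))
  n_hom <- as.integer(colSums(gdel == 2L))
  b_tot <- (n_het + 2 * n_hom) / (2 * L_real)

  # --- expression, RIN, metadata ---
  em <- cfg$expression_model
  rin <- em$rin_intercept + em$rin_y_last * cov$y_last +
    em$rin_b_tot * (b_tot - 0.05) + stats::rnorm(n, 0, em$rin_sd)
  rin <- round(pmin(pmax(rin, 1), 10), 1)
  metadata <- validate_metadata(data.frame(
    sample_id = sample_ids,
    country = sample(cfg$countries, n, replace = TRUE,
                     prob = cfg$country_weights),
    y_acq = cov$y_acq, y_last = cov$y_last, r_cycles = cov$r,
    rin = rin, stringsAsFactors = FALSE
  ))
  expr <- simulate_expression(cfg, ann, is_del_key = del_keys,
                              b_tot = b_tot, metadata = metadata)

  truth <- list(
    del_keys = del_keys, q = q, n_het = n_het, n_hom = n_hom,
    L = L_real, b_tot = b_tot,
    trajectories = do.call(rbind, traj),
    covariates = metadata,
    n_del_dropped_monomorphic = sum(!del_keep),
    n_decoy_dropped_monomorphic = sum(!decoy_keep)
  )
  structure(list(vs = vs, annotation = ann, metadata = metadata,
                 tpm = expr, truth = truth, config = cfg),
            class = "sim_output")
}

simulate_annotation <- function(cfg, sites, is_del) {
  am <- cfg$annotation_model
  n_sites <- nrow(sites)
  gene_pool <- sprintf("GmSIM%04d", seq_len(cfg$n_gene_pool))
  gene_id <- sample(gene_pool, n_sites, replace = TRUE)
  consequence <- character(n_sites)
  sift <- rep(NA_real_, n_sites)
  conf <- rep(NA_character_, n_sites)
  rs <- rep(NA_real_, n_sites)

  # deleterious sites: damaging missense in the constrained track
  idx <- which(is_del)
  consequence[idx] <- "missense_variant"
  sift[idx] <- stats::runif(length(idx), 0, am$sift_del_max * 0.98)
  conf[idx] <- "normal"
  sev <- sample(c("weak", "mild", "high"), length(idx), replace = TRUE,
                prob = am$severity_probs)
  rs[idx] <- ifelse(sev == "weak", stats::runif(length(idx), 0.05, 0.95),
             ifelse(sev == "mild", stats::runif(length(idx), 1, 3),
                    stats::runif(length(idx), 3.05, 6)))

  # decoys: Table-1-like consequence mixture; missense decoys are tolerated
  # or low-confidence SIFT calls; RS partly missing, mostly non-positive
  dec <- which(!is_del)
  weights <- c(synonymous_variant = 20.5, missense_variant = 14,
               `3_prime_UTR_variant` = 7.1, `5_prime_UTR_variant` = 5.4,
               upstream_gene_variant = 1.6, intergenic_variant = 1.1,
               intron_variant = 1.1, downstream_gene_variant = 0.9,
               stop_gained = 0.45, non_coding_transcript_exon_variant = 0.2,
               splice_region_variant = 0.2, splice_donor_variant = 0.05,
               splice_acceptor_variant = 0.05, stop_lost = 0.06,
               start_lost = 0.05, stop_retained_variant = 0.03)
  consequence[dec] <- sample(names(weights), length(dec), replace = TRUE,
                             prob = weights)
  mis <- dec[consequence[dec] == "missense_variant"]
  low <- stats::runif(length(mis)) < cfg$decoy$p_low_confidence
  sift[mis] <- ifelse(low, stats::runif(length(mis), 0, 0.049),
                      stats::runif(length(mis), 0.06, 1))
  conf[mis] <- ifelse(low, "low_confidence", "normal")
  has_rs <- stats::runif(length(dec)) >= cfg$decoy$p_rs_missing
  rs[dec[has_rs]] <- stats::rnorm(sum(has_rs), -1, 1.5)

  annotation_table(data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    gene_id = gene_id, consequence = consequence, sift_score = sift,
    sift_confidence = conf, rs_score = rs, stringsAsFactors = FALSE
  ))
}

simulate_expression <- function(cfg, ann, is_del_key, b_tot, metadata) {
  em <- cfg$expression_model
  del_genes <- unique(ann$gene_id[ann$key %in% is_del_key])
  n_panel <- min(em$n_genes, length(del_genes))
  panel <- sample(del_genes, n_panel)
  n_core <- min(em$n_core, n_panel)
  core <- panel[seq_len(n_core)]
  extra <- setdiff(panel, core)
  # popularity weights so per-gene sample presence spans few-to-all samples
  w <- exp(seq(0, -4, length.out = max(length(extra), 1)))
  n <- nrow(metadata)
  gc <- em$gc_intercept + em$gc_b_tot * (b_tot - 0.05) +
    em$gc_rin * (metadata$rin - 7.7) +
    em$gc_y_acq * (metadata$y_acq - 30) + stats::rnorm(n, 0, em$gc_sd)
  gc <- pmin(pmax(round(gc), n_core), n_panel)
  tpm_target <- em$tpm_intercept + em$tpm_b_tot * (b_tot - 0.05) +
    em$tpm_y_last * (metadata$y_last - 14) +
    em$tpm_gc * (gc - em$gc_intercept) + stats::rnorm(n, 0, em$tpm_sd)
  tpm_target <- pmax(tpm_target, 1)
  gene_mu <- stats::rnorm(n_panel, em$gene_log_mean, em$gene_log_sd)
  names(gene_mu) <- panel
  mat <- matrix(0, n_panel, n, dimnames = list(panel, metadata$sample_id))
  for (j in seq_len(n)) {
    k_extra <- gc[j] - n_core
    on <- c(core, if (k_extra > 0 && length(extra))
      sample(extra, k_extra, prob = w))
    vals <- exp(gene_mu[on] + stats::rnorm(length(on), 0, em$tpm_gene_sd))
    mat[on, j] <- vals * (tpm_target[j] / mean(vals))
  }
  mat
}

#' @export
print.sim_output <- function(x, ...) {
  cat("sim_output:", nrow(x$vs$sites), "SNPs (", x$truth$L,
      "deleterious ) x", length(x$vs$samples), "accessions\n")
  invisible(x)
}

#' Write a simulated dataset to files
#'
#' Emits the genotype VCF (gzip), annotation/metadata/TPM/truth TSVs and the
#' configuration as YAML. Optional "filter fodder" appends extra decoy
#' records to the VCF only (an indel, a multi-allelic site, a low-quality
#' site, a low-depth site, `fodder` of each) so the quality-filter ledger has
#' work to do in end-to-end runs; fodder sites are not annotated.
#'
#' @param sim A `sim_output`.
#' @param dir Output directory (created if needed).
#' @param fodder Number of records per failing class to append (default 0).
#' @return `dir`, invisibly.
#' @export
write_sim_output <- function(sim, dir, fodder = 0) {
  stopifnot(inherits(sim, "sim_output"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- sim$vs
  if (fodder > 0) vs <- add_filter_fodder(vs, fodder)
  write_vcf(vs, file.path(dir, "genotypes.vcf.gz"))
  ann <- sim$annotation
  utils::write.table(ann[, setdiff(names(ann), "key")],
                     file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tpm <- data.frame(gene_id = rownames(sim$tpm), sim$tpm,
                    check.names = FALSE)
  utils::write.table(tpm, file.path(dir, "tpm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(sample_id = sim$metadata$sample_id,
                      n_het = sim$truth$n_het, n_hom = sim$truth$n_hom,
                      L = sim$truth$L, b_tot = sim$truth$b_tot)
  utils::write.table(truth, file.path(dir, "truth_burden.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg$countries <- as.list(cfg$countries)
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

add_filter_fodder <- function(vs, k) {
  n <- length(vs$samples)
  mk <- function(ref, alt, qual, dp_val) {
    list(site = data.frame(chrom = "Chr01",
                           pos = max(vs$sites$pos) + sample.int(1000, k),
                           ref = ref, alt = alt, qual = qual,
                           stringsAsFactors = FALSE),
         geno = matrix(1L, k, n), dp = matrix(dp_val, k, n))
  }
  parts <- list(
    mk("AT", "A", 100, 30L),          # indel
    mk("G", "A,C", 100, 30L),         # multi-allelic (coded het anyway)
    mk("G", "A", 5, 30L),             # below min_qual
    mk("G", "A", 100, 3L)             # below min_dp -> missing -> dropped
  )
  site <- do.call(rbind, lapply(parts, `[[`, "site"))
  site$pos <- max(vs$sites$pos) + seq_len(nrow(site))  # ensure unique
  site$key <- site_key(site$chrom, site$pos, site$ref, site$alt)
  geno <- do.call(rbind, lapply(parts, `[[`, "geno"))
  dp <- do.call(rbind, lapply(parts, `[[`, "dp"))
  new_variant_set(rbind(vs$sites, site), rbind(vs$geno, geno), vs$samples,
                  dp = rbind(vs$dp, dp))
}

#' Run the pipeline on a simulated dataset and check parameter recovery
#'
#' Classifies the simulated annotation, computes burdens on the simulated
#' genotypes, and tests the qualitative behaviour the generative model is
#' built to produce under paper-like parameters: heterozygous and total
#' burden rise significantly with regeneration cycles, homozygous burden
#' does not (purging), and RIN falls with years since the last regeneration.
#'
#' @param sim A `sim_output` from [generate_dataset()].
#' @param alpha Significance level for the slope tests.
#' @return A data.frame of class `recovery_report` (check, slope, p_value,
#'   pass) with the burden table in attribute `"burden"`.
#' @export
recover_parameters <- function(sim, alpha = 0.05) {
  stopifnot(inherits(sim, "sim_output"))
  dset <- classify_deleterious(sim$annotation)
  burden <- compute_burdens(sim$vs, dset)
  m <- sim$metadata[match(burden$sample_id, sim$metadata$sample_id), ]
  r1 <- regress(burden$b_het, m$r_cycles, "b_het", "r_cycles")
  r2 <- regress(burden$b_tot, m$r_cycles, "b_tot", "r_cycles")
  r3 <- regress(burden$b_hom, m$r_cycles, "b_hom", "r_cycles")
  r4 <- regress(m$rin, m$y_last, "rin", "y_last")
  out <- data.frame(
    check = c("b_het_rises_with_regen", "b_tot_rises_with_regen",
              "b_hom_flat_with_regen", "rin_falls_with_y_last"),
    slope = c(r1$slope, r2$slope, r3$slope, r4$slope),
    p_value = c(r1$p_value, r2$p_value, r3$p_value, r4$p_value),
    pass = c(r1$slope > 0 && r1$p_value < alpha,
             r2$slope > 0 && r2$p_value < alpha,
             r3$p_value >= alpha,
             r4$slope < 0 && r4$p_value < alpha)
  )
  attr(out, "burden") <- burden
  class(out) <- c("recovery_report", "data.frame")
  out
}
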