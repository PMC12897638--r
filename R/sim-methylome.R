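#' Generate twin-pair WGBS methylation counts with ground truth
#'
#' Simulates per-CpG methylated/total read counts for `n_pairs` monozygotic
#' twin pairs (one CON and one RES fetus each) under a beta-binomial noise
#' model:
#'
#' * each CpG draws a baseline methylation level from
#'   Beta(`baseline_alpha`, `baseline_beta`);
#' * each pair shares a logit-scale shift drawn from
#'   N(0, `pair_effect_sd`) applied to both twins (the shared gestational
#'   environment of a pair);
#' * a fraction `dm_fraction` of CpGs, placed in clustered runs of mean
#'   length `dm_cluster_size` (differentially methylated regions rather
#'   than isolated sites), carries a true treatment effect: the RES twin's
#'   methylation probability is shifted by
#'   `sign * effect_size * pair_severity[pair]` on the probability scale and
#'   clipped to \[0.001, 0.999\]; the sign is positive with probability
#'   `hyper_fraction` (per cluster);
#' * sequencing depth is negative binomial (zeros allowed) independent of
#'   methylation state, and methylated reads are beta-binomial with
#'   overdispersion `phi`.
#'
#' The exact number of affected CpGs is `round(dm_fraction * n_cpgs)`.
#' Setting `effect_size = 0` yields a pure null data set (`is_dm` all
#' FALSE). The truth table records the realised (post-clipping) per-pair
#' effect, so downstream recovery checks compare against what was actually
#' applied.
#'
#' @param config A [sim_config()].
#' @param features Optional `feature_set` used to attach true region labels
#'   to the truth table.
#' @return A list with elements `counts` (a [count_matrix()]) and `truth`
#'   (data.frame: `chrom`, `pos`, `is_dm`, `true_effect_sign`, one
#'   `effect_pair<i>` column per pair with the realised RES-minus-CON
#'   probability shift, and `region_labels` when `features` is supplied).
#' @examples
#' sim <- gen_twin_methylome(sim_config(n_cpgs = 200, seed = 3))
#' sim$counts
#' @export
gen_twin_methylome <- function(config, features = NULL) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "methylome"))
  n <- config$n_cpgs
  np <- config$n_pairs

  # site positions: even split over chromosomes, unique and sorted
  per_chrom <- diff(round(seq(0, n, length.out = config$n_chroms + 1)))
  if (any(per_chrom > config$chrom_length))
    stop2("n_cpgs exceeds chrom_length: cannot place unique positions")
  sites <- do.call(rbind, lapply(seq_len(config$n_chroms), function(ci) {
    data.frame(chrom = paste0("chr", ci),
               pos = sort(sample.int(config$chrom_length, per_chrom[ci])),
               stringsAsFactors = FALSE)
  }))

  p0 <- clip01(stats::rbeta(n, config$baseline_alpha, config$baseline_beta))

  # clustered placement of true effects; exact count round(dm_fraction * n)
  is_dm <- rep(FALSE, n)
  sign_vec <- rep(NA_real_, n)
  target <- round(config$dm_fraction * n)
  if (config$effect_size > 0 && target > 0) {
    guard <- 0L
    while (sum(is_dm) < target && guard < 100L * target) {
      guard <- guard + 1L
      start <- sample.int(n, 1)
      len <- max(1L, as.integer(round(config$dm_cluster_size)))
      idx <- start:min(start + len - 1L, n)
      idx <- idx[sites$chrom[idx] == sites$chrom[start]]
      idx <- idx[!is_dm[idx]]
      need <- target - sum(is_dm)
      idx <- idx[seq_len(min(length(idx), need))]
      if (!length(idx)) next
      s <- if (stats::runif(1) < config$hyper_fraction) 1 else -1
      is_dm[idx] <- TRUE
      sign_vec[idx] <- s
    }
  }

  pair_shift <- stats::rnorm(np, 0, config$pair_effect_sd)

  samples <- c(paste0("CON", seq_len(np)), paste0("RES", seq_len(np)))
  sheet <- data.frame(sample = samples,
                      group = rep(c("CON", "RES"), each = np),
                      pair = rep(seq_len(np), 2),
                      stringsAsFactors = FALSE)

  p_mat <- matrix(NA_real_, n, 2 * np, dimnames = list(NULL, samples))
  eff <- matrix(0, n, np, dimnames = list(NULL, paste0("effect_pair", seq_len(np))))
  for (j in seq_len(np)) {
    p_con <- clip01(stats::plogis(stats::qlogis(p0) + pair_shift[j]))
    shift <- ifelse(is_dm,
                    sign_vec * config$effect_size * config$pair_severity[j], 0)
    p_res <- clip01(p_con + shift)
    p_mat[, paste0("CON", j)] <- p_con
    p_mat[, paste0("RES", j)] <- p_res
    eff[, j] <- p_res - p_con
  }

  total <- matrix(stats::rnbinom(n * 2 * np, mu = config$mean_depth,
                                 size = config$depth_dispersion),
                  n, 2 * np, dimnames = list(NULL, samples))
  meth <- matrix(0L, n, 2 * np, dimnames = list(NULL, samples))
  for (s in samples) {
    covered <- total[, s] > 0
    meth[covered, s] <- rbetabinom(sum(covered), total[covered, s],
                                   p_mat[covered, s], config$phi)
  }

  truth <- cbind(
    sites,
    data.frame(is_dm = is_dm,
               true_effect_sign = ifelse(is_dm,
                                         ifelse(sign_vec > 0, "+", "-"),
                                         NA_character_),
               stringsAsFactors = FALSE),
    as.data.frame(eff)
  )
  if (!is.null(features)) {
    ann <- annotate_sites(sites, build_interval_index(features))
    truth$region_labels <- ann$labels
  }

  list(counts = count_matrix(sites, meth, total, sheet), truth = truth)
}

#' Generate twin phenotypes (fetal and liver mass)
#'
#' Control twins draw fetal mass and liver-to-body-mass ratio around fixed
#' means with small multiplicative noise; fetal mass of the RES twin is
#' unaffected by treatment, while its liver-to-body ratio is reduced so the
#' pair's expected Liver Sparing Index (LSI, the RES/CON ratio of liver g
#' per kg fetus) equals `1 - lsi_slope * pair_severity[pair]`: pairs with a
#' stronger methylation response show proportionally greater relative liver
#' loss.
#'
#' @param config A [sim_config()].
#' @param truth Ignored; accepted so the generator stages share one calling
#'   convention.
#' @return data.frame with columns `pair`, `group`, `fetal_mass_kg`,
#'   `liver_mass_g`.
#' @export
gen_phenotypes <- function(config, truth = NULL) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "phenotypes"))
  np <- config$n_pairs
  noise <- function(k) 1 + stats::rnorm(k, 0, config$phenotype_noise_sd)

  con_mass <- config$con_fetal_mass_kg * noise(np)
  con_ratio <- config$con_liver_g_per_kg * noise(np)
  res_mass <- con_mass * noise(np)
  lsi_target <- (1 - config$lsi_slope * config$pair_severity) * noise(np)
  res_ratio <- con_ratio * lsi_target

  out <- data.frame(
    pair = rep(seq_len(np), 2),
    group = rep(c("CON", "RES"), each = np),
    fetal_mass_kg = c(con_mass, res_mass),
    liver_mass_g = c(con_ratio * con_mass, res_ratio * res_mass),
    stringsAsFactors = FALSE
  )
  out[order(out$pair, out$group), ]
}
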