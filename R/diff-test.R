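#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated wrapper around `stats::p.adjust(method = "BH")`: sort
#' ascending, `padj_(i) = min_{j >= i} min(1, p_(j) * m / j)`, mapped back
#' to input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed; NA in,
#'   NA out, not counted in `m`).
#' @return Adjusted p-values, elementwise `>= p` and `<= 1`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop2("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Estimate beta-binomial overdispersion
#'
#' Method-of-moments estimate of the intra-class correlation `phi` from
#' within-group variability of per-sample methylation ratios. At each site
#' and group with at least two covered samples, with depths `m_i`, depth
#' weights `w_i = m_i / M`, pooled ratio `p` and per-sample variance
#' `Var(p_i) = p(1-p)(1 + (m_i - 1) phi) / m_i`, the expected weighted
#' residual sum of squares `E[sum (p_i - p_hat)^2]` is linear in `phi`;
#' solving for `phi` gives a numerator/denominator contribution per site.
#' `scope = "genomewide"` pools those contributions over all sites (a
#' precision-weighted mean); `scope = "site"` returns one estimate per
#' site. Estimates are clipped to `[phi_floor, phi_ceiling]`.
#'
#' @param cm A coverage-bearing [count_matrix()].
#' @param scope `"genomewide"` or `"site"`.
#' @param phi_floor,phi_ceiling Clipping bounds (defaults 1e-3 and 0.5).
#' @return A `dispersion_estimate`: list with `phi` (scalar or per-site
#'   vector), `scope`, and the bounds.
#' @export
estimate_dispersion <- function(cm, scope = c("genomewide", "site"),
                                phi_floor = 1e-3, phi_ceiling = 0.5) {
  scope <- match.arg(scope)
  clipf <- function(x) pmin(pmax(x, phi_floor), phi_ceiling)
  n <- nrow(cm$sites)

  # One pass computes, per site and group, the residual sum of squares S
  # and the coefficients of its expectation E[S] = v (A + phi B) with
  # v = p(1 - p), plus the bias coefficients of the plug-in
  # v_hat = p_hat (1 - p_hat), E[v_hat] = v (1 - a - phi b).  phi enters
  # the plug-in correction, so a short fixed-point iteration de-biases it.
  pass <- function(phi_prev) {
    num <- den <- rep(0, n)
    any_info <- rep(FALSE, n)
    for (g in unique(cm$sheet$group)) {
      cols <- cm$sheet$sample[cm$sheet$group == g]
      m <- cm$total[, cols, drop = FALSE]
      x <- cm$meth[, cols, drop = FALSE]
      covd <- m > 0
      ncov <- rowSums(covd)
      use <- ncov >= 2
      if (!any(use)) next
      M <- rowSums(m)
      phat <- rowSums(x) / pmax(M, 1)
      r <- ifelse(covd, x / pmax(m, 1), NA)          # per-sample ratios
      w <- (m / pmax(M, 1)) * covd                   # depth weights
      S <- rowSums((r - phat)^2 * covd, na.rm = TRUE)
      ci <- ((1 - w)^2 + (ncov - 1) * w^2) * covd
      A <- rowSums(ci / pmax(m, 1) * covd, na.rm = TRUE)
      B <- rowSums(ci * (m - 1) / pmax(m, 1), na.rm = TRUE)
      a <- rowSums(w^2 / pmax(m, 1), na.rm = TRUE)   # Var(p_hat) coeffs
      b <- rowSums(w^2 * (m - 1) / pmax(m, 1), na.rm = TRUE)
      vhat <- phat * (1 - phat)
      corr <- pmax(1 - a - phi_prev * b, 0.1)
      v <- vhat / corr
      add <- use & v > 0
      num[add] <- num[add] + (S[add] - v[add] * A[add])
      den[add] <- den[add] + v[add] * B[add]
      any_info <- any_info | add
    }
    if (!any(any_info))
      stop2("no site with >= 2 covered samples in a group: ",
            "cannot estimate dispersion")
    list(num = num, den = den, info = any_info)
  }

  phi_gw <- 0
  for (it in 1:4) {
    p <- pass(phi_gw)
    phi_gw <- clipf(sum(p$num[p$info]) / sum(p$den[p$info]))
  }
  phi <- if (scope == "genomewide") phi_gw else
    ifelse(p$info & p$den > 0, clipf(p$num / pmax(p$den, 1e-12)), NA_real_)
  structure(list(phi = phi, scope = scope,
                 phi_floor = phi_floor, phi_ceiling = phi_ceiling),
            class = "dispersion_estimate")
}

phi_scalar <- function(phi) {
  if (inherits(phi, "dispersion_estimate")) {
    if (phi$scope != "genomewide")
      stop2("a genomewide dispersion estimate is required here")
    phi$phi
  } else as.numeric(phi)
}

#' Group-level beta-binomial Wald test
#'
#' For each CpG, compares depth-weighted mean methylation between the RES
#' and CON groups. Per covered sample with depth `m_i`,
#' `Var(p_i) = p(1-p)(1 + (m_i - 1) phi) / m_i` with `p` the group's pooled
#' ratio; the group mean's variance follows from the weighted-mean formula
#' `sum w_i^2 Var(p_i)` with depth weights. The Wald statistic is
#' `z = (mu_res - mu_con) / sqrt(SE_con^2 + SE_res^2)` referred to a
#' standard normal (two-sided). `meth_diff = mu_res - mu_con`, so positive
#' values mean hypermethylation in the nutrient-restricted group. Sites
#' where both group means are 0 or both are 1 get `p = 1` (zero-variance
#' guard); sites with no covered sample in a group are flagged untestable
#' and excluded from the BH adjustment.
#'
#' @param cm A coverage-filtered [count_matrix()].
#' @param phi Genomewide dispersion ([estimate_dispersion()]) or a scalar.
#' @return data.frame: `chrom`, `pos`, `mu_con`, `mu_res`, `meth_diff`,
#'   `se`, `z`, `p`, `padj`, `status` (`"ok"` or an untestable reason).
#' @export
wald_test_group <- function(cm, phi) {
  phi <- phi_scalar(phi)
  gstat <- lapply(c("CON", "RES"), function(g) {
    cols <- cm$sheet$sample[cm$sheet$group == g]
    m <- cm$total[, cols, drop = FALSE]
    x <- cm$meth[, cols, drop = FALSE]
    M <- rowSums(m)
    mu <- ifelse(M > 0, rowSums(x) / pmax(M, 1), NA_real_)
    v <- mu * (1 - mu)
    w2 <- (m / pmax(M, 1))^2
    var_mu <- rowSums(w2 * v * (1 + (m - 1) * phi) / pmax(m, 1) * (m > 0))
    list(mu = mu, var = ifelse(M > 0, var_mu, NA_real_), M = M)
  })
  con <- gstat[[1]]; res <- gstat[[2]]
  status <- rep("ok", nrow(cm$sites))
  status[con$M == 0 & res$M > 0] <- "no_coverage_con"
  status[res$M == 0 & con$M > 0] <- "no_coverage_res"
  status[con$M == 0 & res$M == 0] <- "no_coverage"
  testable <- status == "ok"

  diff <- res$mu - con$mu
  se <- sqrt(con$var + res$var)
  z <- p <- rep(NA_real_, length(diff))
  pos_se <- testable & se > 0
  z[pos_se] <- diff[pos_se] / se[pos_se]
  p[pos_se] <- 2 * stats::pnorm(-abs(z[pos_se]))
  degen <- testable & se == 0
  z[degen & diff == 0] <- 0
  p[degen & diff == 0] <- 1          # both means 0 or both 1
  z[degen & diff != 0] <- sign(diff[degen & diff != 0]) * Inf
  p[degen & diff != 0] <- 0
  padj <- rep(NA_real_, length(p))
  padj[testable] <- bh_adjust(p[testable])

  data.frame(chrom = cm$sites$chrom, pos = cm$sites$pos,
             mu_con = con$mu, mu_res = res$mu, meth_diff = diff,
             se = se, z = z, p = p, padj = padj, status = status,
             stringsAsFactors = FALSE)
}

#' Single twin-pair beta-binomial Wald test with local smoothing
#'
#' A 1-vs-1 contrast has no replicates, so evidence is pooled over CpGs
#' within `smooth_halfwidth` bp on the same chromosome (the site itself
#' always included), and the genomewide dispersion stands in for a
#' per-site estimate. Each twin's methylation level is estimated as a
#' weighted ratio over the window using precision weights *shared by both
#' twins* — `u_s = 1 / k_s` with
#' `k_s = (1 + (m_con,s - 1) phi) / m_con,s + (1 + (m_res,s - 1) phi) / m_res,s`
#' — so the smoothed RES-minus-CON contrast is the weighted mean of the
#' per-site within-pair ratio differences. Shared weights matter: with
#' twin-specific depth weights the two smoothed estimates average the
#' window's heterogeneous methylation levels differently and the contrast
#' is biased away from zero under the null. The contrast variance is
#' `sum(u_s^2 Var(d_s)) / sum(u_s)^2` with
#' `Var(d_s) = p_s (1 - p_s) k_s`, where `p_s (1 - p_s)` is plugged in
#' from the pooled two-twin site ratio (the null estimate), de-biased for
#' that ratio's own sampling variance; `sum(u_s)` plays the role of an
#' effective window depth. The reported effect
#' `meth_diff_pair` is the smoothed RES-minus-CON contrast (the estimate
#' the statistic is built on, and whose sign it shares); the site's own
#' unsmoothed ratio difference is kept alongside as `site_diff` but is far
#' too noisy at single-twin depth to carry the direction call. A site not
#' covered in both twins is untestable; window sites covered in only one
#' twin do not contribute. BH adjustment is applied within the pair's
#' tested sites.
#'
#' @param cm A coverage-filtered [count_matrix()].
#' @param pair A pair id present in the sample sheet.
#' @param phi Genomewide dispersion ([estimate_dispersion()]) or scalar.
#' @param smooth_halfwidth Smoothing half-window in bp (default 250).
#' @return data.frame: `chrom`, `pos`, `pair`, `meth_diff_pair`, `se`,
#'   `z`, `p`, `padj`, `status`.
#' @export
wald_test_pair <- function(cm, pair, phi, smooth_halfwidth = 250) {
  phi <- phi_scalar(phi)
  sh <- cm$sheet[cm$sheet$pair == pair, ]
  if (nrow(sh) != 2L) stop2("pair '", pair, "' must have exactly two twins")
  s_con <- sh$sample[sh$group == "CON"]
  s_res <- sh$sample[sh$group == "RES"]

  n <- nrow(cm$sites)
  m_c <- cm$total[, s_con]; x_c <- cm$meth[, s_con]
  m_r <- cm$total[, s_res]; x_r <- cm$meth[, s_res]
  both <- m_c > 0 & m_r > 0

  # per-site contrast and shared precision weight (sites covered in both)
  d <- ifelse(both, x_r / pmax(m_r, 1) - x_c / pmax(m_c, 1), 0)
  k <- (1 + (m_c - 1) * phi) / pmax(m_c, 1) +
    (1 + (m_r - 1) * phi) / pmax(m_r, 1)
  u <- ifelse(both, 1 / k, 0)
  # per-site null variance factor p_s (1 - p_s) from the pooled two-twin
  # site ratio, de-biased for the sampling variance of that ratio
  M2 <- m_c + m_r
  p_s <- (x_c + x_r) / pmax(M2, 1)
  cbias <- (m_c / pmax(M2, 1))^2 * (1 + (m_c - 1) * phi) / pmax(m_c, 1) +
    (m_r / pmax(M2, 1))^2 * (1 + (m_r - 1) * phi) / pmax(m_r, 1)
  v_s <- p_s * (1 - p_s) / pmax(1 - cbias, 0.3)

  U <- D <- V <- numeric(n)
  for (ch in unique(cm$sites$chrom)) {
    i <- which(cm$sites$chrom == ch)
    pos <- cm$sites$pos[i]
    lo <- findInterval(pos - smooth_halfwidth - 0.5, pos) + 1L
    hi <- findInterval(pos + smooth_halfwidth + 0.5, pos)
    at <- function(cs, j) ifelse(j >= 1, cs[pmax(j, 1)], 0)
    wsum <- function(v) {
      cs <- cumsum(v[i])
      at(cs, hi) - at(cs, lo - 1L)
    }
    U[i] <- wsum(u)
    D[i] <- wsum(u * d)
    V[i] <- wsum(u * v_s)        # sum u_s^2 Var(d_s) with u_s = 1 / k_s
  }

  status <- rep("ok", n)
  status[!both] <- "no_site_coverage"
  testable <- status == "ok"

  diff <- ifelse(testable, d, NA_real_)
  sm_diff <- ifelse(U > 0, D / pmax(U, 1e-12), NA_real_)
  se <- sqrt(V) / pmax(U, 1e-12)
  z <- p <- rep(NA_real_, n)
  pos_se <- testable & se > 0
  z[pos_se] <- sm_diff[pos_se] / se[pos_se]
  p[pos_se] <- 2 * stats::pnorm(-abs(z[pos_se]))
  degen <- testable & se == 0   # window fully un/methylated in both twins
  z[degen] <- 0
  p[degen] <- 1
  padj <- rep(NA_real_, n)
  padj[testable] <- bh_adjust(p[testable])

  data.frame(chrom = cm$sites$chrom, pos = cm$sites$pos, pair = pair,
             meth_diff_pair = ifelse(testable, sm_diff, NA_real_),
             site_diff = diff, se = se, z = z, p = p, padj = padj,
             status = status, stringsAsFactors = FALSE)
}
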