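#' Derive the two-group diagnosis factor
#'
#' Adds a `group` column contrasting cancerous against non-cancerous sites,
#' with benign sites grouped with normal as "non-cancer" — the two-group
#' contrast used throughout the comparison stage.
#'
#' @param table A cohort table with a `site_type` column
#'   (`cancer` / `normal` / `benign`).
#' @return The table with a `group` factor column (levels `non-cancer`,
#'   `cancer`).
#' @export
add_group <- function(table) {
  table$group <- factor(ifelse(table$site_type == "cancer", "cancer", "non-cancer"),
                        levels = c("non-cancer", "cancer"))
  table
}

#' Random-intercept linear mixed-effects fit
#'
#' Fits `y_ij = x_ij' beta + u_i + e_ij` with a subject random intercept
#' `u_i ~ N(0, sigma_u^2)` and residual `e_ij ~ N(0, sigma_e^2)` by REML,
#' profiling the single variance ratio `gamma = sigma_u^2 / sigma_e^2`
#' (generalized-least-squares `beta` in closed form given `gamma`, bounded
#' one-dimensional search over `gamma` in \[0, 1e6\]). Wald p-values are
#' computed from `beta / se` against the standard normal; the finite-sample
#' alternative is [permutation_test()].
#'
#' The default fixed effects are the two-group diagnosis factor (derived via
#' [add_group()] if absent) and the repeat number entered as a continuous
#' covariate. Any columns of `table` may be named instead; character columns
#' enter as factors, numeric columns as continuous covariates.
#'
#' @param table Cohort tibble with `subject` and the endpoint/fixed-effect
#'   columns.
#' @param endpoint Name of the response column (e.g. `"SO2"`).
#' @param fixed Character vector of fixed-effect column names.
#' @param subject Name of the grouping column for the random intercept.
#' @return An object of class `drs_lmm` with elements `beta`, `se`,
#'   `p_values`, `sigma_u`, `sigma_e`, `gamma`, `logREML`, `n_obs`,
#'   `n_subjects`, and `criterion(gamma)` (the profiled -2 REML criterion, for
#'   optimizer sanity checks). Has [tidy()] and [glance()] methods.
#' @export
fit_lmm <- function(table, endpoint, fixed = c("group", "repeat_idx"),
                    subject = "subject") {
  table <- as.data.frame(table)
  if ("group" %in% fixed && !"group" %in% names(table)) table <- add_group(table)
  need <- c(endpoint, fixed, subject)
  miss <- setdiff(need, names(table))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  table <- table[complete.cases(table[, need]), ]
  y <- as.numeric(table[[endpoint]])
  grp <- factor(table[[subject]])
  if (nlevels(grp) < 2) abort("need at least 2 subjects for a random intercept")

  fx <- table[, fixed, drop = FALSE]
  for (j in seq_along(fx)) if (!is.numeric(fx[[j]])) fx[[j]] <- factor(fx[[j]])
  X <- stats::model.matrix(~ ., data = fx)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste("singular fixed-effect design; aliased columns:",
                paste(aliased, collapse = ", ")),
          class = "drsquant_identifiability_error")
  }
  n <- length(y); p <- ncol(X)
  idx <- split(seq_len(n), grp)

  # GLS profile for a given variance ratio gamma, using the closed-form
  # block inverse (I + gamma J)^-1 = I - gamma/(1 + gamma n_i) J
  profile_gls <- function(gamma) {
    XtVX <- matrix(0, p, p); XtVy <- numeric(p)
    logdet <- 0; yVy <- 0
    for (ix in idx) {
      Xi <- X[ix, , drop = FALSE]; yi <- y[ix]; ni <- length(ix)
      a <- gamma / (1 + gamma * ni)
      cX <- colSums(Xi); cy <- sum(yi)
      XtVX <- XtVX + crossprod(Xi) - a * tcrossprod(cX)
      XtVy <- XtVy + crossprod(Xi, yi) - a * cX * cy
      yVy <- yVy + sum(yi^2) - a * cy^2
      logdet <- logdet + log1p(gamma * ni)
    }
    beta <- solve(XtVX, XtVy)
    rss <- yVy - sum(beta * XtVy)
    list(beta = beta, rss = rss, logdet = logdet, XtVX = XtVX)
  }
  criterion <- function(gamma) {
    g <- profile_gls(gamma)
    (n - p) * log(g$rss / (n - p)) + g$logdet +
      determinant(g$XtVX, logarithm = TRUE)$modulus[1] +
      (n - p) * (1 + log(2 * pi))
  }
  opt <- optimize(function(lg) criterion(exp(lg)), interval = c(-15, log(1e6)))
  cand <- rbind(c(0, criterion(0)), c(exp(opt$minimum), opt$objective))
  gamma <- cand[which.min(cand[, 2]), 1]
  g <- profile_gls(gamma)
  sigma_e2 <- g$rss / (n - p)
  se <- sqrt(diag(solve(g$XtVX)) * sigma_e2)
  beta <- drop(g$beta)
  names(beta) <- names(se) <- colnames(X)
  z <- beta / se
  structure(list(
    beta = beta, se = se, statistic = z,
    p_values = pmax(2 * pnorm(-abs(z)), .Machine$double.xmin),
    sigma_u = sqrt(gamma * sigma_e2), sigma_e = sqrt(sigma_e2),
    gamma = gamma, logREML = -0.5 * criterion(gamma),
    criterion = criterion,
    n_obs = n, n_subjects = nlevels(grp),
    endpoint = endpoint, fixed = fixed
  ), class = "drs_lmm")
}

#' @export
print.drs_lmm <- function(x, ...) {
  cat("<drs_lmm> endpoint:", x$endpoint, " (", x$n_obs, "obs,",
      x$n_subjects, "subjects )\n")
  print(data.frame(estimate = x$beta, se = x$se, z = x$statistic,
                   p = signif(x$p_values, 3)))
  cat(sprintf("sigma_u = %.4g, sigma_e = %.4g, logREML = %.4g\n",
              x$sigma_u, x$sigma_e, x$logREML))
  invisible(x)
}

#' Tidy a mixed-effects fit
#'
#' @param x A `drs_lmm`.
#' @param ... Unused.
#' @return One row per fixed effect: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.drs_lmm <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std.error = unname(x$se), statistic = unname(x$statistic),
         p.value = unname(x$p_values))
}

#' @rdname tidy.drs_lmm
#' @export
glance.drs_lmm <- function(x, ...) {
  tibble(sigma_u = x$sigma_u, sigma_e = x$sigma_e, logREML = x$logREML,
         n_obs = x$n_obs, n_subjects = x$n_subjects)
}

#' Permutation test of the group effect
#'
#' Distribution-free check of the mixed-model Wald test: the two-group labels
#' are permuted across subject-site units (each site keeps its repeats
#' intact), the group-effect z statistic is recomputed for each permutation,
#' and `p = (1 + #{|T_perm| >= |T_obs|}) / (1 + n_perm)`. When fewer distinct
#' site-label arrangements exist than `n_perm`, the complete enumeration is
#' used instead (noted in the `"method"` attribute).
#'
#' @param table Cohort tibble (see [fit_lmm()]).
#' @param endpoint Response column name.
#' @param n_perm Number of permutations (>= 199; default 999).
#' @param seed Integer seed.
#' @return The p-value, with attributes `"method"` (`"sampled"` or `"exact"`),
#'   `"n"` (permutations used) and `"statistic"` (observed z).
#' @export
permutation_test <- function(table, endpoint, n_perm = 999, seed = 1) {
  if (n_perm < 199) abort("n_perm must be at least 199")
  table <- as.data.frame(add_group(table))
  sites <- unique(table[, c("subject", "site_type")])
  site_key <- paste(table$subject, table$site_type)
  sites$key <- paste(sites$subject, sites$site_type)
  labels <- factor(ifelse(sites$site_type == "cancer", "cancer", "non-cancer"),
                   levels = c("non-cancer", "cancer"))
  n_sites <- nrow(sites); n_cancer <- sum(labels == "cancer")

  stat <- function(site_labels) {
    table$group <- site_labels[match(site_key, sites$key)]
    fit <- fit_lmm(table, endpoint, fixed = intersect(c("group", "repeat_idx"),
                                                      names(table)))
    unname(fit$statistic[grep("^group", names(fit$beta))[1]])
  }
  t_obs <- stat(labels)

  n_distinct <- choose(n_sites, n_cancer)
  if (n_distinct <= n_perm) {
    combos <- utils::combn(n_sites, n_cancer)
    t_perm <- apply(combos, 2, function(ix) {
      lab <- factor(rep("non-cancer", n_sites), levels = levels(labels))
      lab[ix] <- "cancer"
      stat(lab)
    })
    p <- mean(abs(t_perm) >= abs(t_obs) - 1e-12)
    return(structure(p, method = "exact", n = ncol(combos), statistic = t_obs))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  t_perm <- replicate(n_perm, stat(sample(labels)))
  p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
  structure(p, method = "sampled", n = n_perm, statistic = t_obs)
}

#' One-way ANOVA on per-site mean endpoints
#'
#' Aggregates repeats to per-site means (sites as independent units) and runs
#' a one-way analysis of variance of the endpoint across groups — the
#' inter-group variance check accompanying the mixed model.
#'
#' @param table Cohort tibble.
#' @param endpoint Response column name.
#' @param groups Grouping column (default the two-group diagnosis factor,
#'   derived if absent).
#' @return A one-row tibble with `statistic` (F), `p.value`, `df1`, `df2`.
#' @export
anova_groups <- function(table, endpoint, groups = "group") {
  table <- as.data.frame(table)
  if (groups == "group" && !"group" %in% names(table)) table <- add_group(table)
  per_site <- stats::aggregate(
    table[[endpoint]],
    by = list(subject = table$subject, site_type = table$site_type,
              g = table[[groups]]),
    FUN = mean
  )
  tab <- table(per_site$g)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("ANOVA needs >= 2 groups with >= 2 sites each (degrees of freedom)",
          class = "drsquant_df_error")
  }
  a <- stats::anova(stats::lm(x ~ g, data = per_site))
  f <- a$`F value`[1]; pv <- a$`Pr(>F)`[1]
  if (a$`Sum Sq`[1] <= 1e-300) { f <- 0; pv <- 1 }   # degenerate equal-groups case
  tibble(statistic = f, p.value = pv, df1 = a$Df[1], df2 = a$Df[2])
}
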