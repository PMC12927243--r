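# Generalized additive models of per-fish network metrics against fork
# length and origin, with time-at-liberty class as a random intercept.

#' Fit size/origin models for a family of network metrics
#'
#' For each metric, fits a penalized-spline GAM of the log-transformed
#' metric (log, or log(1 + x) when zeros are present) on a smooth of
#' fork length plus an origin contrast, with the time-at-liberty class
#' as a random intercept (`s(liberty_class, bs = "re")`). When the
#' random-intercept variance degenerates (effective df near zero) the
#' model is refit with the class as a fixed factor and flagged. Basis
#' dimension adequacy is checked and `k` doubled (at most twice) when
#' the check fails.
#'
#' @param metric_table Per-fish table with `fork_length_mm`, `origin`,
#'   `liberty_class` and the metric columns.
#' @param metrics Character vector of metric column names.
#' @param k Initial basis dimension of the length smooth.
#' @param alpha Significance level.
#' @return List of class `coastnet_metric_models` with `results` (one
#'   row per metric x term: estimate or edf, p value, Holm-adjusted p,
#'   direction, significance, transform, k used, fallback flag,
#'   rows dropped) and `fits` (named list of gam objects).
#' @export
fit_metric_models <- function(metric_table,
                              metrics = c("mean_degree", "mean_graph_strength",
                                          "edge_count", "edge_density",
                                          "average_path_length",
                                          "max_degree_centrality",
                                          "max_betweenness_centrality",
                                          "residency_index", "sum_distance_km"),
                              k = 5, alpha = 0.05) {
  metrics <- intersect(metrics, names(metric_table))
  if (!length(metrics)) {
    abort_coastnet("no metric columns found in metric_table", "coastnet_data_error")
  }
  metric_table$origin <- factor(metric_table$origin)
  metric_table$liberty_class <- factor(metric_table$liberty_class)
  fits <- list(); rows <- list()
  for (m in metrics) {
    dat <- metric_table[, c(m, "fork_length_mm", "origin", "liberty_class")]
    names(dat)[1] <- "y"
    transform <- if (any(dat$y == 0, na.rm = TRUE)) "log1p" else "log"
    dat$yt <- if (transform == "log1p") log1p(dat$y) else log(dat$y)
    ok <- stats::complete.cases(dat) & is.finite(dat$yt)
    n_dropped <- sum(!ok)
    dat <- dat[ok, ]
    dat$liberty_class <- droplevels(dat$liberty_class)
    dat$origin <- droplevels(dat$origin)
    use_origin <- nlevels(dat$origin) >= 2
    use_re <- nlevels(dat$liberty_class) >= 2

    if (sd(dat$yt) < 1e-10) {
      # degenerate: no variance to model
      rows[[length(rows) + 1]] <- tibble::tibble(
        metric = m, term = "s(fork_length_mm)", estimate = 0,
        statistic = "edf", p_value = NA_real_, direction = 0,
        transform = transform, k_used = k, re_fallback = FALSE,
        n = nrow(dat), n_dropped = n_dropped)
      next
    }
    fit <- fit_one_gam(dat, k = k, use_origin = use_origin, use_re = use_re,
                       re_fixed = FALSE)
    fallback <- FALSE
    if (use_re && re_edf(fit) < 0.05) {
      fit <- fit_one_gam(dat, k = fit$coastnet_k, use_origin = use_origin,
                         use_re = TRUE, re_fixed = TRUE)
      fallback <- TRUE
    }
    fits[[m]] <- fit
    sm <- summary(fit)
    st <- sm$s.table
    len_row <- grep("fork_length", rownames(st))
    len_edf <- unname(st[len_row, "edf"])
    len_p <- unname(st[len_row, ncol(st)])
    dir <- smooth_direction(fit, dat)
    rows[[length(rows) + 1]] <- tibble::tibble(
      metric = m, term = "s(fork_length_mm)", estimate = len_edf,
      statistic = "edf", p_value = len_p, direction = dir,
      transform = transform, k_used = fit$coastnet_k,
      re_fallback = fallback, n = nrow(dat), n_dropped = n_dropped)
    if (use_origin) {
      pt <- sm$p.table
      or_row <- grep("^origin", rownames(pt))[1]
      rows[[length(rows) + 1]] <- tibble::tibble(
        metric = m, term = rownames(pt)[or_row],
        estimate = unname(pt[or_row, "Estimate"]), statistic = "coef",
        p_value = unname(pt[or_row, ncol(pt)]),
        direction = sign(pt[or_row, "Estimate"]),
        transform = transform, k_used = fit$coastnet_k,
        re_fallback = fallback, n = nrow(dat), n_dropped = n_dropped)
    }
    if (use_re) {
      if (fallback) {
        a <- stats::anova(fit)
        lp <- a$pTerms.table[grep("liberty", rownames(a$pTerms.table)), "p-value"]
        est <- NA_real_
      } else {
        re_row <- grep("liberty", rownames(st))
        est <- unname(st[re_row, "edf"])
        lp <- unname(st[re_row, ncol(st)])
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        metric = m, term = "liberty_class", estimate = est,
        statistic = if (fallback) "F-test" else "edf", p_value = unname(lp),
        direction = NA_real_, transform = transform, k_used = fit$coastnet_k,
        re_fallback = fallback, n = nrow(dat), n_dropped = n_dropped)
    }
  }
  results <- dplyr::bind_rows(rows)
  results <- results |>
    dplyr::group_by(.data$term) |>
    dplyr::mutate(p_holm = stats::p.adjust(.data$p_value, method = "holm")) |>
    dplyr::ungroup()
  results$significant <- results$p_value < alpha
  structure(list(results = results, fits = fits, alpha = alpha),
            class = "coastnet_metric_models")
}

# One gam fit with k-adequacy doubling.
fit_one_gam <- function(dat, k, use_origin, use_re, re_fixed) {
  k_now <- k
  for (attempt in 1:3) {
    rhs <- sprintf("s(fork_length_mm, k = %d)", k_now)
    if (use_origin) rhs <- paste(rhs, "+ origin")
    if (use_re) {
      rhs <- paste(rhs, if (re_fixed) "+ liberty_class" else
        '+ s(liberty_class, bs = "re")')
    }
    fit <- mgcv::gam(stats::as.formula(paste("yt ~", rhs)), data = dat,
                     method = "REML")
    kc <- tryCatch(mgcv::k.check(fit), error = function(e) NULL)
    if (is.null(kc)) break
    lr <- grep("fork_length", rownames(kc))
    if (!length(lr)) break
    k_index <- kc[lr, "k-index"]
    p_kc <- kc[lr, "p-value"]
    if (is.na(k_index) || k_index >= 1 || is.na(p_kc) || p_kc >= 0.05) break
    if (k_now >= nrow(dat) / 2) break
    k_now <- k_now * 2
  }
  fit$coastnet_k <- k_now
  fit
}

re_edf <- function(fit) {
  st <- summary(fit)$s.table
  r <- grep("liberty", rownames(st))
  if (!length(r)) return(Inf)
  unname(st[r, "edf"])
}

# Sign of the fitted length effect: slope of the partial smooth across
# the observed range (finite difference over a grid).
smooth_direction <- function(fit, dat) {
  rng <- range(dat$fork_length_mm)
  grid <- ref_newdata(fit, dat, seq(rng[1], rng[2], length.out = 25))
  pr <- stats::predict(fit, newdata = grid, type = "terms")
  col <- grep("fork_length", colnames(pr))
  f <- pr[, col]
  unname(sign(f[length(f)] - f[1]))
}

ref_newdata <- function(fit, dat, lengths) {
  nd <- data.frame(fork_length_mm = lengths)
  if ("origin" %in% names(fit$model)) nd$origin <- levels(dat$origin)[1]
  if ("liberty_class" %in% names(fit$model)) {
    nd$liberty_class <- levels(dat$liberty_class)[1]
  }
  nd
}

#' Partial-effect curves of the length smooth
#'
#' Predictions over a fork-length grid at the reference origin and
#' liberty level, random intercept excluded, with pointwise ~95%
#' intervals. Grid points outside the observed length range are flagged
#' as extrapolation.
#'
#' @param models A `coastnet_metric_models`.
#' @param metric_table The table the models were fitted to.
#' @param lengths Optional grid (default: 50 points over the observed
#'   range).
#' @return Tibble: `metric`, `fork_length_mm`, `fit` (link scale),
#'   `se`, `lower`, `upper`, `extrapolated`.
#' @export
partial_effect_curves <- function(models, metric_table, lengths = NULL) {
  obs_rng <- range(metric_table$fork_length_mm, na.rm = TRUE)
  if (is.null(lengths)) lengths <- seq(obs_rng[1], obs_rng[2], length.out = 50)
  metric_table$origin <- factor(metric_table$origin)
  metric_table$liberty_class <- factor(metric_table$liberty_class)
  out <- lapply(names(models$fits), function(m) {
    fit <- models$fits[[m]]
    nd <- ref_newdata(fit, metric_table, lengths)
    excl <- if (any(grepl("liberty", sapply(fit$smooth, `[[`, "label")))) {
      "s(liberty_class)"
    } else NULL
    pr <- stats::predict(fit, newdata = nd, type = "link", se.fit = TRUE,
                         exclude = excl, newdata.guaranteed = TRUE)
    tibble::tibble(metric = m, fork_length_mm = lengths,
                   fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
                   lower = as.numeric(pr$fit - 1.96 * pr$se.fit),
                   upper = as.numeric(pr$fit + 1.96 * pr$se.fit),
                   extrapolated = lengths < obs_rng[1] | lengths > obs_rng[2])
  })
  dplyr::bind_rows(out)
}

#' Mean slope of the fitted length effect
#'
#' Average finite-difference slope of the partial length smooth on the
#' link (log) scale, comparable to a simulated log-scale slope per mm.
#'
#' @param models A `coastnet_metric_models`.
#' @param metric_table The fitted table.
#' @param metric Metric name (default: first fitted metric).
#' @return Numeric slope (log units per mm).
#' @export
length_effect_slope <- function(models, metric_table,
                                metric = names(models$fits)[1]) {
  cv <- partial_effect_curves(models, metric_table)
  cv <- cv[cv$metric == metric, ]
  unname(coef(stats::lm(fit ~ fork_length_mm, data = cv))[2])
}

#' Simulate a per-fish metric table from a known generative model
#'
#' Draws fork lengths uniformly over the study size range, assigns
#' origins and liberty classes, and generates one metric from
#' `log(metric) = intercept + slope * length + origin_effect * I(sea) +
#' b[liberty_class] + noise`, for power and type-I-error checks of
#' [fit_metric_models()].
#'
#' @param n Number of fish.
#' @param slope Log-scale length effect per mm.
#' @param sigma Residual SD on the log scale.
#' @param origin_effect Log-scale sea-vs-lagoon offset.
#' @param liberty_sd SD of the liberty-class random intercepts.
#' @param intercept Log-scale intercept.
#' @param size_range_mm Fork-length range.
#' @param metric_name Name of the generated metric column.
#' @param seed RNG seed.
#' @return Tibble with covariates and the metric column; true values in
#'   `attr(, "truth")`.
#' @export
simulate_metric_table <- function(n = 200, slope = 0.005, sigma = 0.3,
                                  origin_effect = 0, liberty_sd = 0.1,
                                  intercept = 0, size_range_mm = c(182, 650),
                                  metric_name = "mean_degree", seed = 1L) {
  with_seed(seed, {
    fl <- runif(n, size_range_mm[1], size_range_mm[2])
    origin <- sample(c("lagoon", "sea"), n, replace = TRUE)
    lc <- sample(c("short", "medium", "long", "very_long"), n, replace = TRUE)
    b <- setNames(rnorm(4, 0, liberty_sd),
                  c("short", "medium", "long", "very_long"))
    ly <- intercept + slope * fl + origin_effect * (origin == "sea") +
      b[lc] + rnorm(n, 0, sigma)
    out <- tibble::tibble(tag_id = sprintf("sim_%03d", seq_len(n)),
                          fork_length_mm = fl, origin = origin,
                          liberty_class = lc)
    out[[metric_name]] <- exp(ly)
    attr(out, "truth") <- list(slope = slope, origin_effect = origin_effect,
                               sigma = sigma, intercept = intercept)
    out
  })
}
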