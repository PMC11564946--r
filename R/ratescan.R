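#' Rate-versus-age points from an annotated tree
#'
#' Extracts the (node age, node rate) scatter underlying a rate-time
#' analysis. Two conventions are supported for the node rate:
#'
#' * `"annotation"` — the `rate_median` annotation carried by the tree, i.e.
#'   what an MCC summary tree actually stores at each node;
#' * `"median_of_adjacent"` — the median of the rates of the three branches
#'   adjacent to the node (parent edge and the two child edges; the root uses
#'   the median of its child edges only). This requires per-branch rates
#'   (`branch_rate` annotations), which simulator output carries.
#'
#' Tips (age 0) are excluded by default: their ages carry no temporal signal
#' for the rate-time trend.
#'
#' @param tree An [annotated_tree].
#' @param node_rate_mode `"annotation"` or `"median_of_adjacent"`.
#' @param include_tips Include leaf nodes as points.
#' @return A data frame with columns `node_id`, `age_ma`, `rate`
#'   (substitutions/site/Myr). Nodes with missing rates are dropped; the
#'   number dropped is reported in attribute `"n_dropped"` and via a message.
#' @export
rate_age_points <- function(tree,
                            node_rate_mode = c("annotation", "median_of_adjacent"),
                            include_tips = FALSE) {
  stopifnot(inherits(tree, "annotated_tree"))
  node_rate_mode <- match.arg(node_rate_mode)
  nd <- tree$node_data
  phy <- tree$phy
  n <- ape::Ntip(phy)
  rate <- if (node_rate_mode == "annotation") {
    nd$rate_median
  } else {
    if (all(is.na(nd$branch_rate)))
      stop("median_of_adjacent mode requires per-branch rates ",
           "('branch_rate' annotations)")
    vapply(nd$node, function(v) {
      adjacent <- nd$branch_rate[v]               # parent edge (NA at root)
      kids <- phy$edge[phy$edge[, 1L] == v, 2L]
      adjacent <- c(adjacent, nd$branch_rate[kids])
      adjacent <- adjacent[!is.na(adjacent)]
      if (length(adjacent) == 0L) NA_real_ else stats::median(adjacent)
    }, numeric(1))
  }
  keep <- if (include_tips) rep(TRUE, nrow(nd)) else nd$node > n
  pts <- data.frame(node_id = nd$label[keep], age_ma = nd$age_ma[keep],
                    rate = rate[keep], stringsAsFactors = FALSE)
  n_dropped <- sum(is.na(pts$rate))
  if (n_dropped > 0L)
    message("rate_age_points: dropped ", n_dropped, " node(s) with missing rates")
  pts <- pts[!is.na(pts$rate), , drop = FALSE]
  if (nrow(pts) == 0L)
    stop("no usable (age, rate) points: all rates missing")
  rownames(pts) <- NULL
  attr(pts, "n_dropped") <- n_dropped
  pts
}

#' Fit the exponential rate-time model
#'
#' Fits `r(t) = r0 * exp(b * t)` to (age, rate) points by ordinary least
#' squares of `log(rate)` on age — the spreadsheet "exponential trendline"
#' estimator. With ages in Ma before present, `b < 0` means the rate decays
#' into the past, i.e. increases toward the present. A fixed-intercept
#' variant constrains `r0` to a given value (for example a posterior mean
#' clock rate) and regresses `log(rate) - log(r0)` on age through the
#' origin.
#'
#' @param points Data frame with columns `age_ma` and `rate` (e.g. from
#'   [rate_age_points()]), or a two-column matrix/data frame of (age, rate).
#' @param intercept_mode `"free"` (default) or `"fixed"`.
#' @param fixed_intercept The constrained `r0` in substitutions/site/Myr
#'   (required when `intercept_mode = "fixed"`).
#' @param nonlinear_refine Refine the log-linear estimates by nonlinear
#'   least squares on the natural scale (Levenberg-Marquardt via
#'   [stats::nls()]); the log-linear fit remains the reference estimator.
#' @return An object of class `"rate_time_fit"`: a list with `r0`, `b`,
#'   `r_squared` (on the log-linear scale), `n_points`, `intercept_mode`,
#'   `fixed_intercept_value`, and the fitted `points`.
#' @examples
#' pts <- data.frame(age_ma = c(0, 10, 20), rate = 0.02 * exp(-0.05 * c(0, 10, 20)))
#' fit_exponential(pts)
#' @export
fit_exponential <- function(points, intercept_mode = c("free", "fixed"),
                            fixed_intercept = NULL, nonlinear_refine = FALSE) {
  intercept_mode <- match.arg(intercept_mode)
  if (is.matrix(points)) points <- as.data.frame(points)
  if (!all(c("age_ma", "rate") %in% names(points))) {
    if (ncol(points) >= 2L) names(points)[1:2] <- c("age_ma", "rate")
    else stop("'points' must have columns age_ma and rate")
  }
  age <- as.numeric(points$age_ma)
  rate <- as.numeric(points$rate)
  if (any(!is.finite(age)) || any(!is.finite(rate)))
    stop("non-finite age or rate in points")
  if (any(rate <= 0)) {
    bad <- which(rate <= 0)
    lab <- if ("node_id" %in% names(points)) points$node_id[bad] else bad
    stop("non-positive rate(s) at: ", paste(lab, collapse = ", "),
         "; the exponential model requires rate > 0")
  }
  y <- log(rate)

  if (intercept_mode == "free") {
    if (length(unique(age)) < 2L)
      stop("free-intercept fit needs at least 2 distinct ages")
    xb <- mean(age); yb <- mean(y)
    sxx <- sum((age - xb)^2)
    b <- sum((age - xb) * (y - yb)) / sxx
    a <- yb - b * xb
    resid <- y - (a + b * age)
    sst <- sum((y - yb)^2)
    r2 <- if (sst > 0) 1 - sum(resid^2) / sst else 1
    r0 <- exp(a)
    fixed_val <- NA_real_
  } else {
    if (is.null(fixed_intercept) || !is.numeric(fixed_intercept) ||
        fixed_intercept <= 0)
      stop("intercept_mode='fixed' requires a positive 'fixed_intercept'")
    if (length(age) < 1L || all(age == 0))
      stop("fixed-intercept fit needs at least one point with age > 0")
    y0 <- y - log(fixed_intercept)
    b <- sum(age * y0) / sum(age^2)
    r0 <- fixed_intercept
    resid <- y0 - b * age
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(resid^2) / sst else 1
    fixed_val <- fixed_intercept
  }

  if (nonlinear_refine) {
    start <- list(r0 = r0, b = b)
    nl <- tryCatch(
      stats::nls(rate ~ r0 * exp(b * age), data = data.frame(age = age, rate = rate),
                 start = start),
      error = function(e) NULL)
    if (!is.null(nl) && intercept_mode == "free") {
      cf <- stats::coef(nl)
      r0 <- unname(cf["r0"]); b <- unname(cf["b"])
    }
  }

  structure(list(r0 = r0, b = b, r_squared = r2, n_points = length(age),
                 intercept_mode = intercept_mode,
                 fixed_intercept_value = fixed_val,
                 points = data.frame(age_ma = age, rate = rate)),
            class = "rate_time_fit")
}

#' Predicted rate at a given age
#'
#' @param object A [fit_exponential()] result.
#' @param age_ma Ages (Ma) at which to evaluate `r(t) = r0 * exp(b * t)`.
#' @param ... Unused.
#' @return Numeric vector of rates in substitutions/site/Myr.
#' @export
predict.rate_time_fit <- function(object, age_ma, ...) {
  object$r0 * exp(object$b * age_ma)
}

#' @export
print.rate_time_fit <- function(x, ...) {
  cat("Exponential rate-time fit: r(t) = r0 * exp(b * t)\n")
  cat(sprintf("  r0 = %.6g s/s/Myr (%s intercept)%s\n", x$r0, x$intercept_mode,
              if (x$intercept_mode == "fixed")
                sprintf(" [fixed at %.6g]", x$fixed_intercept_value) else ""))
  cat(sprintf("  b  = %.6g per Myr (%s)\n", x$b,
              if (x$b < 0) "rate increases toward the present"
              else if (x$b > 0) "rate decreases toward the present"
              else "constant rate"))
  cat(sprintf("  r^2 (log-linear) = %.4f on %d points\n", x$r_squared, x$n_points))
  invisible(x)
}

#' Tabular and graphical rate-time report
#'
#' Writes the (age, rate) point table, samples of the fitted curve, and a
#' fit summary; optionally a scatter-with-curve figure.
#'
#' @param points Data frame from [rate_age_points()].
#' @param fit A [fit_exponential()] result.
#' @param out_dir Output directory (created if needed).
#' @param n_curve Number of fitted-curve samples across the age range.
#' @param figure Format of the optional figure: `"none"`, `"png"`, or
#'   `"svg"`.
#' @return Invisibly, a named character vector of the files written.
#' @export
rate_report <- function(points, fit, out_dir, n_curve = 100L,
                        figure = c("none", "png", "svg")) {
  stopifnot(inherits(fit, "rate_time_fit"))
  figure <- match.arg(figure)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  pt_path <- file.path(out_dir, "rate_age_points.tsv")
  utils::write.table(points, pt_path, sep = "\t", quote = FALSE, row.names = FALSE)
  files["points"] <- pt_path

  age_range <- range(points$age_ma)
  if (diff(age_range) == 0) age_range <- age_range + c(0, 1)
  curve_age <- seq(age_range[1L], age_range[2L], length.out = n_curve)
  curve <- data.frame(age_ma = curve_age,
                      rate_fitted = predict(fit, curve_age))
  cv_path <- file.path(out_dir, "rate_age_curve.tsv")
  utils::write.table(curve, cv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  files["curve"] <- cv_path

  summ <- c(
    "# exponential rate-time fit: r(t) = r0 * exp(b * t); ages in Ma, rates in s/s/Myr",
    paste0("r0\t", .fmt_num(fit$r0)),
    paste0("b\t", .fmt_num(fit$b)),
    paste0("r_squared_log\t", .fmt_num(fit$r_squared)),
    paste0("n_points\t", fit$n_points),
    paste0("intercept_mode\t", fit$intercept_mode),
    paste0("fixed_intercept_value\t",
           if (is.na(fit$fixed_intercept_value)) "NA"
           else .fmt_num(fit$fixed_intercept_value))
  )
  sm_path <- file.path(out_dir, "rate_fit_summary.tsv")
  writeLines(summ, sm_path)
  files["summary"] <- sm_path

  if (figure != "none") {
    fig_path <- file.path(out_dir, paste0("rate_age_scatter.", figure))
    if (figure == "png") grDevices::png(fig_path, width = 800, height = 600)
    else grDevices::svg(fig_path, width = 8, height = 6)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(points$age_ma, points$rate,
                   xlab = "Node age (Ma)",
                   ylab = "Rate median (substitutions/site/Myr)",
                   main = "Substitution rate vs node age", pch = 19,
                   col = grDevices::adjustcolor("black", 0.6))
    graphics::lines(curve$age_ma, curve$rate_fitted, col = "red", lwd = 2)
    graphics::legend("topright", bty = "n", legend = sprintf(
      "r(t) = %.4g e^{%.4g t}, r2 = %.3f", fit$r0, fit$b, fit$r_squared))
    files["figure"] <- fig_path
  }
  invisible(files)
}
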