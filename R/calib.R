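#' Construct a tMRCA calibration point
#'
#' A calibration point fixes a normal prior on the age of the most recent
#' common ancestor (tMRCA) of a clade, in the minimum-age sense: the oldest
#' fossil assignable to the clade (or a dated geological event) gives the
#' prior mean, and the dating uncertainty gives the prior SD. Ages are in Ma
#' (million years before present) throughout.
#'
#' @param id Unique calibration label, e.g. `"A2"` or `"Q7"`.
#' @param ingroup_taxa Character vector of taxon labels defining the clade.
#' @param placement `"crown"` (MRCA node of the ingroup) or `"stem"` (the
#'   parent of that MRCA).
#' @param prior_mean Prior mean age in Ma; must be positive.
#' @param prior_sd Prior SD in Ma; must be non-negative.
#' @param evidence One of `"fossil_stage"` (age from a geological stage
#'   assignment), `"fossil_dated"` (radio-isotopic or fission-track date of
#'   the fossil horizon), or `"geological_event"` (dated vicariance or island
#'   emergence event).
#' @param monophyletic Whether the ingroup is constrained monophyletic.
#' @param active Whether the calibration is in use; transcription fixtures
#'   keep superseded ("not applied") rows with `active = FALSE`.
#' @return An object of class `"calibration_point"`.
#' @seealso [prior_from_stage()], [prior_from_date()], [load_calibration_table()]
#' @export
calibration_point <- function(id, ingroup_taxa, placement = c("crown", "stem"),
                              prior_mean, prior_sd,
                              evidence = c("fossil_stage", "fossil_dated",
                                           "geological_event"),
                              monophyletic = TRUE, active = TRUE) {
  placement <- match.arg(placement)
  evidence <- match.arg(evidence)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a single non-empty string")
  ingroup_taxa <- as.character(ingroup_taxa)
  if (length(ingroup_taxa) == 0L || any(!nzchar(ingroup_taxa)))
    stop("calibration '", id, "': 'ingroup_taxa' must be non-empty labels")
  if (!is.numeric(prior_mean) || length(prior_mean) != 1L ||
      !is.finite(prior_mean) || prior_mean <= 0)
    stop("calibration '", id, "': 'prior_mean' must be a positive age in Ma")
  if (!is.numeric(prior_sd) || length(prior_sd) != 1L ||
      !is.finite(prior_sd) || prior_sd < 0)
    stop("calibration '", id, "': 'prior_sd' must be a non-negative SD in Ma")
  structure(
    list(id = id, ingroup_taxa = ingroup_taxa, placement = placement,
         prior_mean = as.numeric(prior_mean), prior_sd = as.numeric(prior_sd),
         evidence = evidence, monophyletic = isTRUE(monophyletic),
         active = isTRUE(active)),
    class = "calibration_point"
  )
}

#' @export
print.calibration_point <- function(x, ...) {
  cat(sprintf("Calibration %s [%s, %s%s]: %g +/- %g Ma; ingroup: %s\n",
              x$id, x$placement, x$evidence,
              if (x$active) "" else ", inactive",
              x$prior_mean, x$prior_sd,
              paste(x$ingroup_taxa, collapse = ", ")))
  invisible(x)
}

#' Normal prior from geological stage bounds
#'
#' Converts the absolute-age bounds of a geological stage (from the ICS
#' chronostratigraphic chart) into a normal tMRCA prior: the mean is the
#' stage midpoint and the SD the half-range, so that mean +/- SD recovers
#' the bounds exactly. This is the convention behind stage-based fossil
#' calibrations such as "Hettangian age (200.3 +/- 1.0 Ma)" from bounds
#' 201.3-199.3 Ma.
#'
#' @param older_bound Older (larger) stage bound in Ma.
#' @param younger_bound Younger (smaller) stage bound in Ma.
#' @param stage_name Optional stage label carried through for reporting.
#' @return A list with `prior_mean`, `prior_sd` (Ma) and `stage_name`.
#' @examples
#' prior_from_stage(201.3, 199.3)   # 200.3 +/- 1.0 Ma (Hettangian)
#' prior_from_stage(33.9, 28.1)     # 31.0 +/- 2.9 Ma (Rupelian)
#' @export
prior_from_stage <- function(older_bound, younger_bound, stage_name = NA_character_) {
  if (!is.numeric(older_bound) || !is.numeric(younger_bound) ||
      length(older_bound) != 1L || length(younger_bound) != 1L ||
      !is.finite(older_bound) || !is.finite(younger_bound))
    stop("stage bounds must be single finite ages in Ma")
  if (younger_bound < 0)
    stop("younger stage bound must be >= 0 Ma (got ", younger_bound, ")")
  if (older_bound <= younger_bound)
    stop("older bound (", older_bound, " Ma) must exceed younger bound (",
         younger_bound, " Ma); zero-width or inverted stages are not valid")
  list(prior_mean = (older_bound + younger_bound) / 2,
       prior_sd = (older_bound - younger_bound) / 2,
       stage_name = stage_name)
}

#' Normal prior from a radio-isotopic or event date
#'
#' Validates a directly dated horizon (U-Pb, Ar-Ar, K-Ar, fission track) or a
#' dated geological event as a normal tMRCA prior. Unlike
#' [prior_from_stage()] the mean and SD are taken as published, e.g. the
#' Burmese amber U-Pb age 98.79 +/- 0.62 Ma.
#'
#' @param mean Published mean age in Ma (> 0).
#' @param sd Published SD in Ma (>= 0).
#' @param evidence `"fossil_dated"` or `"geological_event"`.
#' @return A list with `prior_mean`, `prior_sd` and `evidence`.
#' @examples
#' prior_from_date(98.79, 0.62)
#' prior_from_date(1.55, 0.15, evidence = "geological_event")
#' @export
prior_from_date <- function(mean, sd, evidence = c("fossil_dated", "geological_event")) {
  evidence <- match.arg(evidence)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("dated prior mean must be a positive age in Ma (got ", mean, ")")
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("dated prior SD must be non-negative (got ", sd, ")")
  list(prior_mean = as.numeric(mean), prior_sd = as.numeric(sd),
       evidence = evidence)
}

.calib_header <- c("id", "ingroup_taxa", "placement", "prior_mean_ma",
                   "prior_sd_ma", "evidence", "active")

#' Read a calibration table
#'
#' Reads a tab-separated calibration table with header
#' `id  ingroup_taxa  placement  prior_mean_ma  prior_sd_ma  evidence  active`
#' (ages in Ma; taxa separated by `|`) into a list of calibration points.
#' The packaged fixture `system.file("extdata", "table2_calibrations.tsv",
#' package = "cicadaclock")` transcribes the cicada/Hemiptera calibration
#' set used with this convention, including superseded rows kept with
#' `active = FALSE`.
#'
#' @param path Path to the TSV file.
#' @return A list of [calibration_point()] objects, in file order. An empty
#'   file (header only) yields an empty list.
#' @export
load_calibration_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, .calib_header))
    stop("calibration table header must be: ",
         paste(.calib_header, collapse = "  "))
  rows <- lines[-1L]
  if (length(rows) == 0L) return(list())
  errors <- character(0)
  out <- vector("list", length(rows))
  seen <- character(0)
  for (i in seq_along(rows)) {
    f <- strsplit(rows[[i]], "\t", fixed = TRUE)[[1L]]
    row_err <- function(msg) sprintf("row %d: %s", i + 1L, msg)
    if (length(f) != length(.calib_header)) {
      errors <- c(errors, row_err(sprintf("expected %d fields, found %d",
                                          length(.calib_header), length(f))))
      next
    }
    cp <- tryCatch(
      calibration_point(
        id = f[[1L]],
        ingroup_taxa = strsplit(f[[2L]], "|", fixed = TRUE)[[1L]],
        placement = f[[3L]],
        prior_mean = as.numeric(f[[4L]]),
        prior_sd = as.numeric(f[[5L]]),
        evidence = f[[6L]],
        active = identical(tolower(f[[7L]]), "true")
      ),
      error = function(e) conditionMessage(e),
      warning = function(w) conditionMessage(w)
    )
    if (is.character(cp)) {
      errors <- c(errors, row_err(cp))
      next
    }
    if (cp$id %in% seen) {
      errors <- c(errors, row_err(sprintf("duplicate id '%s'", cp$id)))
      next
    }
    seen <- c(seen, cp$id)
    out[[i]] <- cp
  }
  if (length(errors) > 0L)
    stop("calibration table '", path, "' has invalid rows:\n  ",
         paste(errors, collapse = "\n  "))
  out[!vapply(out, is.null, logical(1))]
}

# Fixed decimal formatting: all calibration ages in the fixture have at most
# four decimals, so %.4f round-trips exactly and keeps serialization
# byte-stable.
.format_ma <- function(x) sprintf("%.4f", x)

#' Write a calibration table
#'
#' Serializes calibration points to the tab-separated format read by
#' [load_calibration_table()], in canonical form: rows sorted by id
#' (byte-order collation) and ages printed with four fixed decimals, so
#' load-then-write is byte-stable.
#'
#' @param cals List of [calibration_point()] objects.
#' @param path Output path; if `NULL` the lines are returned invisibly
#'   without writing.
#' @return Invisibly, the character vector of file lines.
#' @export
write_calibration_table <- function(cals, path = NULL) {
  stopifnot(all(vapply(cals, inherits, logical(1), "calibration_point")))
  ids <- vapply(cals, `[[`, character(1), "id")
  cals <- cals[order(ids, method = "radix")]
  body <- vapply(cals, function(cp) {
    paste(cp$id,
          paste(cp$ingroup_taxa, collapse = "|"),
          cp$placement,
          .format_ma(cp$prior_mean),
          .format_ma(cp$prior_sd),
          cp$evidence,
          if (cp$active) "true" else "false",
          sep = "\t")
  }, character(1))
  lines <- c(paste(.calib_header, collapse = "\t"), body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Locate the tree node a calibration applies to
#'
#' Resolves a calibration's clade definition on a tree: `crown` placement
#' maps to the MRCA node of the ingroup taxa (the leaf itself when the
#' ingroup is a single taxon); `stem` maps to the parent of that MRCA node.
#'
#' @param tree An [annotated_tree] or an `ape` `phylo` object.
#' @param cal A [calibration_point()].
#' @return The node number (ape convention: tips `1..n`, internals
#'   `(n+1)..(2n-1)`).
#' @export
resolve_calibrated_node <- function(tree, cal) {
  phy <- as_phylo(tree)
  stopifnot(inherits(cal, "calibration_point"))
  missing_taxa <- setdiff(cal$ingroup_taxa, phy$tip.label)
  if (length(missing_taxa) > 0L)
    stop("calibration '", cal$id, "': taxa not in tree: ",
         paste(missing_taxa, collapse = ", "))
  tips <- match(cal$ingroup_taxa, phy$tip.label)
  mrca <- if (length(tips) == 1L) tips else ape::getMRCA(phy, tips)
  if (cal$placement == "crown") return(mrca)
  root <- ape::Ntip(phy) + 1L
  if (mrca == root)
    stop("calibration '", cal$id, "': stem placement requested but the ",
         "ingroup MRCA is the root; no parent node exists")
  phy$edge[phy$edge[, 2L] == mrca, 1L]
}

#' Check posterior node ages against calibration priors
#'
#' For each calibration, finds its node on a dated tree and compares the
#' posterior node age with the normal prior via the z-score
#' `(age - prior_mean) / prior_sd`. Under minimum-age semantics a posterior
#' age far *below* the prior mean signals a violated calibration, so nodes
#' with `z < -z_tol` are flagged. Calibrations whose taxa are absent from the
#' tree are reported as `"unresolvable"` rather than raising an error.
#'
#' @param tree An [annotated_tree].
#' @param cals List of [calibration_point()] objects.
#' @param z_tol Flagging threshold on the z-score (default 3).
#' @param include_inactive Also check rows with `active = FALSE`.
#' @return A data frame with one row per checked calibration: `id`, `status`
#'   (`"ok"`, `"flagged"`, or `"unresolvable"`), `node`, `prior_mean_ma`,
#'   `prior_sd_ma`, `posterior_age_ma`, `z`.
#' @export
check_posterior_vs_prior <- function(tree, cals, z_tol = 3, include_inactive = FALSE) {
  stopifnot(inherits(tree, "annotated_tree"))
  if (inherits(cals, "calibration_point")) cals <- list(cals)
  if (!include_inactive)
    cals <- Filter(function(cp) cp$active, cals)
  ages <- node_ages(tree)
  rows <- lapply(cals, function(cp) {
    node <- tryCatch(resolve_calibrated_node(tree, cp), error = function(e) NA_integer_)
    if (is.na(node)) {
      return(data.frame(id = cp$id, status = "unresolvable", node = NA_integer_,
                        prior_mean_ma = cp$prior_mean, prior_sd_ma = cp$prior_sd,
                        posterior_age_ma = NA_real_, z = NA_real_,
                        stringsAsFactors = FALSE))
    }
    age <- ages[[node]]
    z <- if (cp$prior_sd > 0) (age - cp$prior_mean) / cp$prior_sd
         else if (age == cp$prior_mean) 0
         else sign(age - cp$prior_mean) * Inf
    data.frame(id = cp$id, status = if (z < -z_tol) "flagged" else "ok",
               node = node, prior_mean_ma = cp$prior_mean,
               prior_sd_ma = cp$prior_sd, posterior_age_ma = age, z = z,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Sample ages from a calibration prior
#'
#' Draws from the normal tMRCA prior truncated at 0 Ma (ages cannot be
#' negative); used to parameterize simulations, not for inference.
#'
#' @param cal A [calibration_point()].
#' @param n Number of draws.
#' @return Numeric vector of ages in Ma.
#' @export
sample_calibration_prior <- function(cal, n = 1L) {
  stopifnot(inherits(cal, "calibration_point"), n >= 1)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, cal$prior_mean, cal$prior_sd)
    out <- c(out, draw[draw >= 0])
  }
  out[seq_len(n)]
}
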