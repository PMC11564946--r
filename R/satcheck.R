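#' Read an aligned FASTA file
#'
#' Loads a nucleotide alignment into an upper-case character matrix (taxa in
#' rows, sites in columns). Sequences must be of equal length.
#'
#' @param path FASTA file path.
#' @return Character matrix with taxon row names.
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  m <- toupper(as.character(as.matrix(dna)))
  rownames(m) <- names(dna)
  m
}

.as_char_alignment <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1L && file.exists(alignment))
    return(read_alignment(alignment))
  if (inherits(alignment, "DNAbin")) {
    if (is.list(alignment)) {
      if (length(unique(lengths(alignment))) != 1L) stop("ragged alignment")
      alignment <- as.matrix(alignment)
    }
    return(toupper(as.character(alignment)))
  }
  if (is.matrix(alignment) && is.character(alignment))
    return(toupper(alignment))
  if (is.character(alignment)) {
    # vector of equal-length sequence strings
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L) stop("ragged alignment")
    m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
    rownames(m) <- names(alignment)
    return(m)
  }
  stop("unsupported alignment representation")
}

.PURINES <- c("A", "G")
.PYRIMIDINES <- c("C", "T")

#' Count transitions and transversions between two aligned sequences
#'
#' Sites where either sequence carries anything other than an unambiguous
#' A/C/G/T (gaps, Ns, IUPAC ambiguities) are excluded pairwise. Transitions
#' are A<->G and C<->T; all other base differences are transversions.
#'
#' @param seq_a,seq_b Equal-length character vectors of bases, or single
#'   strings.
#' @return A list with `ti`, `tv`, and `n_compared`.
#' @examples
#' count_ti_tv("ACGT", "GCGA")  # one transition (A/G), one transversion (T/A)
#' @export
count_ti_tv <- function(seq_a, seq_b) {
  if (is.character(seq_a) && length(seq_a) == 1L)
    seq_a <- strsplit(seq_a, "", fixed = TRUE)[[1L]]
  if (is.character(seq_b) && length(seq_b) == 1L)
    seq_b <- strsplit(seq_b, "", fixed = TRUE)[[1L]]
  if (length(seq_a) != length(seq_b))
    stop("sequence length mismatch: ", length(seq_a), " vs ", length(seq_b))
  a <- toupper(seq_a); b <- toupper(seq_b)
  valid <- a %in% c(.PURINES, .PYRIMIDINES) & b %in% c(.PURINES, .PYRIMIDINES)
  a <- a[valid]; b <- b[valid]
  diff <- a != b
  ti <- sum(diff & ((a %in% .PURINES & b %in% .PURINES) |
                    (a %in% .PYRIMIDINES & b %in% .PYRIMIDINES)))
  tv <- sum(diff) - ti
  list(ti = ti, tv = tv, n_compared = sum(valid))
}

#' Kimura two-parameter corrected distance
#'
#' Evaluates `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where `P` and `Q`
#' are the transition and transversion proportions. Outside the admissible
#' region (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the pair is saturated and the
#' distance is returned as `NA` rather than an error. For small divergences
#' `d` approaches `P + Q`, the p-distance.
#'
#' @param P Transition proportion(s).
#' @param Q Transversion proportion(s).
#' @return Corrected distance(s); `NA` where undefined (saturated).
#' @examples
#' k2p_distance(0.1, 0.05)
#' @export
k2p_distance <- function(P, Q) {
  if (any(P < 0 | Q < 0, na.rm = TRUE))
    stop("P and Q must be non-negative proportions")
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  out <- ifelse(w1 > 0 & w2 > 0,
                -0.5 * log(pmax(w1, .Machine$double.xmin)) -
                  0.25 * log(pmax(w2, .Machine$double.xmin)),
                NA_real_)
  out
}

#' Tamura-Nei 1993 corrected distance
#'
#' Distinguishes purine (A<->G) and pyrimidine (C<->T) transitions and uses
#' the (average) base frequencies of the compared pair. Returned as `NA`
#' where a logarithm argument is non-positive (saturated pair).
#'
#' @param P1 Purine-transition proportion (A<->G).
#' @param P2 Pyrimidine-transition proportion (C<->T).
#' @param Q Transversion proportion.
#' @param base_freqs Numeric vector of frequencies named A, C, G, T.
#' @return Corrected distance, or `NA` when undefined.
#' @export
tn93_distance <- function(P1, P2, Q, base_freqs) {
  stopifnot(length(base_freqs) == 4L)
  if (is.null(names(base_freqs))) names(base_freqs) <- c("A", "C", "G", "T")
  f <- base_freqs / sum(base_freqs)
  gR <- f[["A"]] + f[["G"]]
  gY <- f[["C"]] + f[["T"]]
  k1 <- 2 * f[["A"]] * f[["G"]] / gR
  k2 <- 2 * f[["C"]] * f[["T"]] / gY
  k3 <- 2 * (gR * gY - f[["A"]] * f[["G"]] * gY / gR -
               f[["C"]] * f[["T"]] * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (any(c(w1, w2, w3) <= 0)) return(NA_real_)
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

#' All-pairs transition/transversion saturation table
#'
#' Computes, for every unordered pair of sequences in an alignment, the
#' transition and transversion counts, the number of unambiguously compared
#' sites, the p-distance, and a model-corrected distance. Pairs whose
#' corrected distance is undefined (saturated) are retained with
#' `saturated = TRUE` rather than dropped, so saturation stays visible.
#'
#' @param alignment A FASTA path, `DNAbin` object, character matrix, or
#'   vector of equal-length sequence strings.
#' @param model Distance correction: `"k2p"` (default) or `"tn93"`.
#' @return A data frame of class `"saturation_table"`, one row per pair in
#'   deterministic (row-major) order: `taxon_a`, `taxon_b`, `n_compared`,
#'   `ti`, `tv`, `ti_per_site`, `tv_per_site`, `p_dist`, `d_corrected`
#'   (model in attribute `"model"`), `saturated`.
#' @export
saturation_table <- function(alignment, model = c("k2p", "tn93")) {
  model <- match.arg(model)
  m <- .as_char_alignment(alignment)
  n <- nrow(m)
  if (n < 2L) stop("saturation table needs at least 2 sequences")
  taxa <- rownames(m)
  if (is.null(taxa)) taxa <- paste0("seq", seq_len(n))
  # alignment-wide base frequencies over unambiguous sites (the convention
  # of standard TN93 implementations)
  global_freqs <- table(factor(m[m %in% c(.PURINES, .PYRIMIDINES)],
                               levels = c("A", "C", "G", "T")))
  pairs <- utils::combn(n, 2L)
  records <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    a <- m[i, ]; b <- m[j, ]
    valid <- a %in% c(.PURINES, .PYRIMIDINES) & b %in% c(.PURINES, .PYRIMIDINES)
    av <- a[valid]; bv <- b[valid]
    nc <- length(av)
    diff <- av != bv
    ti1 <- sum(diff & av %in% .PURINES & bv %in% .PURINES)
    ti2 <- sum(diff & av %in% .PYRIMIDINES & bv %in% .PYRIMIDINES)
    ti <- ti1 + ti2
    tv <- sum(diff) - ti
    p <- if (nc > 0) sum(diff) / nc else NA_real_
    d <- if (nc == 0) NA_real_
    else if (model == "k2p") k2p_distance(ti / nc, tv / nc)
    else tn93_distance(ti1 / nc, ti2 / nc, tv / nc, as.numeric(global_freqs))
    records[[k]] <- data.frame(
      taxon_a = taxa[i], taxon_b = taxa[j], n_compared = nc,
      ti = ti, tv = tv,
      ti_per_site = if (nc > 0) ti / nc else NA_real_,
      tv_per_site = if (nc > 0) tv / nc else NA_real_,
      p_dist = p, d_corrected = d,
      saturated = is.na(d) & nc > 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  attr(out, "model") <- model
  class(out) <- c("saturation_table", class(out))
  out
}

#' Binned-slope plateau statistic
#'
#' Operationalizes a saturation check on a transition/transversion versus
#' corrected-distance scatter: records are binned by corrected distance, the
#' marginal slope of the transition (and transversion) count against
#' distance is computed within each bin, and the trend of those slopes
#' across bins is summarized by a Spearman rank correlation in `[-1, 1]`.
#' A clearly negative transition trend means the transition curve flattens
#' with distance — the classic saturation signal; a trend near 0 means the
#' accumulation stays linear (no saturation).
#'
#' @param records A [saturation_table()] (saturated pairs, which have no
#'   finite corrected distance, are excluded from binning).
#' @param n_bins Number of equal-width distance bins (default 10).
#' @return A list with `ti_trend`, `tv_trend` (rank-correlation trend
#'   statistics), and `bins`, a data frame of per-bin midpoints, counts, and
#'   slopes.
#' @export
plateau_statistic <- function(records, n_bins = 10L) {
  stopifnot(is.data.frame(records),
            all(c("ti", "tv", "d_corrected") %in% names(records)))
  ok <- is.finite(records$d_corrected)
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) < 2L * n_bins)
    stop("plateau_statistic needs at least 2 * n_bins (= ", 2L * n_bins,
         ") records with finite corrected distances; got ", nrow(rec))
  d <- rec$d_corrected
  if (diff(range(d)) <= 0)
    stop("corrected distances have no spread; cannot bin")
  breaks <- seq(min(d), max(d), length.out = n_bins + 1L)
  bin <- cut(d, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  slope_in_bin <- function(y, idx) {
    x <- d[idx]
    if (length(idx) < 2L || stats::var(x) == 0) return(NA_real_)
    stats::cov(x, y[idx]) / stats::var(x)
  }
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  bins <- data.frame(bin = seq_len(n_bins), d_mid = mids,
                     n = as.integer(tabulate(bin, nbins = n_bins)))
  bins$ti_slope <- vapply(seq_len(n_bins), function(g)
    slope_in_bin(rec$ti, which(bin == g)), numeric(1))
  bins$tv_slope <- vapply(seq_len(n_bins), function(g)
    slope_in_bin(rec$tv, which(bin == g)), numeric(1))
  usable <- is.finite(bins$ti_slope)
  if (sum(usable) < 3L)
    stop("fewer than 3 bins with estimable slopes; increase the number of ",
         "records or reduce n_bins")
  trend <- function(slopes) {
    u <- is.finite(slopes)
    s <- slopes[u]
    # constant slopes (up to numerical noise) mean no curvature: trend 0
    if (stats::sd(s) <= 1e-9 * max(abs(s), .Machine$double.eps)) return(0)
    stats::cor(bins$d_mid[u], s, method = "spearman")
  }
  list(ti_trend = trend(bins$ti_slope),
       tv_trend = trend(bins$tv_slope),
       bins = bins)
}

#' Write a saturation table as TSV
#'
#' @param records A [saturation_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_saturation_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Saturation scatter figure
#'
#' Plots transition and transversion counts against corrected distance, the
#' standard visual saturation diagnostic.
#'
#' @param records A [saturation_table()].
#' @param path Output figure path (`.png` or `.svg`).
#' @return Invisibly, `path`.
#' @export
plot_saturation <- function(records, path) {
  if (grepl("\\.svg$", path)) grDevices::svg(path, width = 8, height = 6)
  else grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off(), add = TRUE)
  ok <- is.finite(records$d_corrected)
  graphics::plot(records$d_corrected[ok], records$ti[ok], pch = 19,
                 col = grDevices::adjustcolor("blue", 0.5),
                 xlab = "Corrected pairwise distance",
                 ylab = "Number of base changes",
                 main = "Transitions and transversions vs corrected distance",
                 ylim = range(c(records$ti[ok], records$tv[ok])))
  graphics::points(records$d_corrected[ok], records$tv[ok], pch = 17,
                   col = grDevices::adjustcolor("darkgreen", 0.5))
  graphics::legend("topleft", bty = "n", pch = c(19, 17),
                   col = c("blue", "darkgreen"),
                   legend = c("transitions", "transversions"))
  invisible(path)
}
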