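#' Load the packaged clinical Cobb-angle measurement table
#'
#' Returns the packaged table of Cobb angles for 35 AP-view radiographs
#' measured by an expert and a novice orthopedist (two sessions each) and
#' by the automatic minimum-bounding-rectangle method, together with the
#' chosen end-vertebra labels.  "No scoliosis" assessments carry an angle
#' of 0 and a flag, the convention used throughout the agreement analysis.
#' The file's checksum is verified on load.
#'
#' @param path override the packaged fixture path (checksum then skipped).
#' @return data frame with one row per image: angle columns `expert_t1`,
#'   `expert_t2`, `novice_t1`, `novice_t2`, `mbr`, end-vertebra label
#'   columns, and the no-scoliosis flags.
#' @export
load_table4 <- function(path = NULL) {
  checked <- is.null(path)
  if (is.null(path))
    path <- system.file("extdata", "table4_cobb.csv", package = "spinecobb",
                        mustWork = TRUE)
  if (checked) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, table4_md5))
      stop("measurement table fixture is corrupted (checksum mismatch)")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(d) == 35)
  d
}

# frozen checksum of inst/extdata/table4_cobb.csv
table4_md5 <- "205fcd2f20440326ed55e05bc68a2561"

#' Descriptive statistics with population standard deviation
#'
#' @param x numeric vector, length at least 2.
#' @return list with `mean`, `sd` (population form, n denominator), `min`,
#'   `max`, `n`.
#' @export
descriptive <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  list(mean = mean(x), sd = sqrt(mean((x - mean(x))^2)),
       min = min(x), max = max(x), n = length(x))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input")
  stats::cor(x, y)
}

#' Spearman rank-order correlation
#'
#' Ranks both vectors (average ranks on ties) and evaluates the
#' rank-difference form `rho = 1 - 6 sum(d^2) / (n (n^2 - 1))`.  That
#' closed form assumes untied ranks; when ties are present the function
#' falls back to the Pearson correlation of the ranks (to which the
#' closed form is identical in the untied case).
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  ties <- anyDuplicated(rx) || anyDuplicated(ry)
  if (ties) return(stats::cor(rx, ry))
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition across independent groups.
#'
#' @param groups list of numeric vectors (at least 2 groups of at least 2
#'   values each).
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  list(F = s[1, "F value"], p = s[1, "Pr(>F)"],
       df_between = s[1, "Df"], df_within = s[2, "Df"])
}

#' Intraclass correlation coefficient
#'
#' Computed from the two-way (subjects x raters) ANOVA mean squares.  The
#' default form is the two-way random-effects, absolute-agreement,
#' single-measure coefficient ICC(2,1); the consistency form ICC(3,1) is
#' also available.
#'
#' @param m numeric matrix, subjects in rows, raters in columns (no
#'   missing cells).
#' @param form `"ICC(2,1)"` (absolute agreement, default) or `"ICC(3,1)"`
#'   (consistency).
#' @return the coefficient.
#' @export
icc <- function(m, form = c("ICC(2,1)", "ICC(3,1)")) {
  form <- match.arg(form)
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("missing cells are not supported")
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 raters")
  subj <- rowMeans(m); rat <- colMeans(m); g <- mean(m)
  MSR <- k * sum((subj - g)^2) / (n - 1)
  MSC <- n * sum((rat - g)^2) / (k - 1)
  SSE <- sum((m - g)^2) - k * sum((subj - g)^2) - n * sum((rat - g)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (form == "ICC(2,1)")
    (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  else
    (MSR - MSE) / (MSR + (k - 1) * MSE)
}

#' Qualitative band of an intraclass correlation coefficient
#'
#' Bands: poor below 0.40, fair 0.40-0.59, good 0.60-0.74, excellent
#' 0.75-1.00.
#'
#' @param value coefficient in [-1, 1].
#' @return character band.
#' @export
classify_icc <- function(value) {
  stopifnot(value >= -1, value <= 1)
  if (value < 0.40) "poor"
  else if (value < 0.60) "fair"
  else if (value < 0.75) "good"
  else "excellent"
}

#' Observer-agreement report for the measurement table
#'
#' Recomputes the full agreement battery from the measurement table:
#' per-group descriptive statistics (mean, population sd, min, max),
#' one-way ANOVA across the three measurement sources, and pairwise
#' Pearson, Spearman and intraclass correlations.  Manual observers
#' contribute the chosen session's measurements (`session = 1` by
#' default); the automatic method has a single measurement per image.
#'
#' @param records data frame from [load_table4()].
#' @param session manual-measurement session, 1 or 2.
#' @param icc_form passed to [icc()].
#' @return list with `groups` (descriptives), `anova`, and `pairs` (data
#'   frame of pairwise coefficients and ICC bands).
#' @export
agreement_report <- function(records, session = 1,
                             icc_form = "ICC(2,1)") {
  stopifnot(session %in% c(1, 2))
  cols <- c(expert = paste0("expert_t", session),
            novice = paste0("novice_t", session), mbr = "mbr")
  vals <- lapply(cols, function(cn) records[[cn]])
  groups <- lapply(vals, descriptive)
  aov_res <- one_way_anova(unname(vals))
  pair_names <- list(c("expert", "novice"), c("expert", "mbr"),
                     c("novice", "mbr"))
  pairs <- do.call(rbind, lapply(pair_names, function(pn) {
    x <- vals[[pn[1]]]; y <- vals[[pn[2]]]
    v <- icc(cbind(x, y), form = icc_form)
    data.frame(pair = paste(pn, collapse = "-"),
               pearson = pearson_r(x, y),
               spearman = spearman_rho(x, y),
               icc = v, icc_band = classify_icc(v))
  }))
  list(groups = groups, anova = aov_res, pairs = pairs,
       session = session, icc_form = icc_form)
}
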