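#' FIB-4 liver fibrosis score
#'
#' `FIB-4 = (age [years] x AST [U/L]) / (platelets [10^9/L] x sqrt(ALT [U/L]))`.
#' Inputs must be positive; with `allow_zero_ast = TRUE` an AST of zero is
#' permitted and yields a score of 0.
#'
#' @param age,ast,alt,platelets clinical measurements (vectorised).
#' @param allow_zero_ast permit AST = 0 (default FALSE: validation error).
#' @return numeric vector of scores.
#' @examples
#' fib4Score(60, 40, 40, 150)  # 2.530
#' @export
fib4Score <- function(age, ast, alt, platelets, allow_zero_ast = FALSE) {
  if (any(age <= 0, na.rm = TRUE) || any(alt <= 0, na.rm = TRUE) ||
      any(platelets <= 0, na.rm = TRUE)) {
    stop("age, ALT and platelets must be positive", call. = FALSE)
  }
  if (any(ast < 0, na.rm = TRUE) ||
      (!allow_zero_ast && any(ast == 0, na.rm = TRUE))) {
    stop("AST must be positive (set allow_zero_ast = TRUE to permit 0)",
         call. = FALSE)
  }
  (age * ast) / (platelets * sqrt(alt))
}

.LSM_BANDS <- c(8, 15)
.FIB4_BANDS <- c(1.3, 3.2)

#' Stratify patients by liver stiffness or FIB-4 score
#'
#' LSM bands: low < 8 kPa; 8 <= intermediate <= 15; high > 15 kPa. FIB-4
#' bands: low < 1.3; 1.3 <= intermediate <= 3.2; high > 3.2. Values exactly
#' at a boundary are assigned to the middle band (closed middle), making the
#' three bands a partition. Records with a missing value get NA and their
#' count is logged.
#'
#' @param records patient data.frame with columns `lsm_kpa` (for `by =
#'   "lsm"`) or `age`, `ast`, `alt`, `platelets` (for `by = "fib4"`; a
#'   precomputed `fib4` column is used if present).
#' @param by stratification variable.
#' @return factor with levels `low`, `intermediate`, `high` (NA for missing
#'   values), with the score used stored in attribute `score`.
#' @examples
#' stratifyPatients(data.frame(lsm_kpa = c(7.99, 8, 15, 15.01)))
#' @export
stratifyPatients <- function(records, by = c("lsm", "fib4")) {
  by <- match.arg(by)
  if (by == "lsm") {
    stopifnot("lsm_kpa" %in% names(records))
    x <- records$lsm_kpa
    bands <- .LSM_BANDS
  } else {
    x <- if ("fib4" %in% names(records)) records$fib4 else
      fib4Score(records$age, records$ast, records$alt, records$platelets)
    bands <- .FIB4_BANDS
  }
  n_missing <- sum(is.na(x))
  if (n_missing > 0L) {
    message(n_missing, " record(s) with missing ", by, " excluded")
  }
  g <- ifelse(is.na(x), NA_character_,
              ifelse(x < bands[1L], "low",
                     ifelse(x <= bands[2L], "intermediate", "high")))
  out <- factor(g, levels = c("low", "intermediate", "high"))
  attr(out, "score") <- x
  out
}

# round half up to one decimal, matching printed clinical style
.round_half_up1 <- function(x) floor(x * 10 + 0.5) / 10

#' Count and percentage summary of a label vector
#'
#' Percentages are of the total record count, rounded half-up to one
#' decimal; a total row is appended. Labels absent from the data (levels of
#' a factor) are reported as 0 (0.0%).
#'
#' @param labels character or factor vector (one element per record).
#' @return data.frame with columns `label`, `n`, `percent`.
#' @examples
#' cohortSummary(rep(c("NAFLD", "other"), c(134, 62)))
#' @export
cohortSummary <- function(labels) {
  if (length(labels) == 0L) stop("at least one record required", call. = FALSE)
  counts <- table(labels, useNA = "no")
  total <- length(labels)
  out <- data.frame(label = names(counts), n = as.integer(counts),
                    percent = .round_half_up1(100 * as.integer(counts) / total),
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(label = "total", n = total, percent = 100))
}

#' Kruskal-Wallis comparison with Dunn post-hoc tests
#'
#' Kruskal-Wallis H (tie-corrected, asymptotic chi-square p) across the
#' groups, followed by Dunn's pairwise z-tests on mean ranks with tie
#' correction, adjusted for the C(k, 2) comparisons by Bonferroni (default,
#' matching common GraphPad behaviour) or Holm. When every value is
#' identical the comparison is degenerate: H = 0, p = 1.
#'
#' @param values numeric response (e.g. serum biomarker).
#' @param groups group labels, coercible to factor; every group needs at
#'   least 2 values.
#' @param adjust multiplicity adjustment for the Dunn tests.
#' @return object of class `stratifiedComparison`: a list with `grouping`
#'   (per-group n, median, IQR), `H`, `p`, `pairwise` (z, raw and adjusted
#'   p per pair) and `adjust`.
#' @examples
#' compareGroups(1:9, rep(c("a", "b", "c"), each = 3))
#' @export
compareGroups <- function(values, groups, adjust = c("bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  ns <- table(groups)
  if (any(ns < 2L)) {
    stop("every group needs at least 2 values (violated by: ",
         paste(names(ns)[ns < 2L], collapse = ", "), ")", call. = FALSE)
  }
  grouping <- data.frame(
    group = levels(groups),
    n = as.integer(ns),
    median = as.numeric(tapply(values, groups, stats::median)),
    iqr = as.numeric(tapply(values, groups, stats::IQR)),
    stringsAsFactors = FALSE
  )
  pairs <- utils::combn(levels(groups), 2L)
  if (length(unique(values)) == 1L) {
    H <- 0; p <- 1
    pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                     z = 0, p = 1, p_adj = 1, stringsAsFactors = FALSE)
  } else {
    kt <- stats::kruskal.test(values, groups)
    H <- unname(kt$statistic)
    p <- kt$p.value
    r <- rank(values)
    N <- length(values)
    rbar <- tapply(r, groups, mean)
    ties <- table(values)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    sigma2 <- N * (N + 1) / 12 - tie_term
    z <- vapply(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
      (rbar[[g1]] - rbar[[g2]]) /
        sqrt(sigma2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    }, numeric(1))
    praw <- 2 * stats::pnorm(-abs(z))
    padj <- if (adjust == "bonferroni") {
      pmin(1, praw * ncol(pairs))
    } else {
      stats::p.adjust(praw, method = "holm")
    }
    pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                     z = z, p = praw, p_adj = padj,
                     stringsAsFactors = FALSE)
  }
  structure(list(grouping = grouping, H = H, p = p, pairwise = pw,
                 adjust = adjust),
            class = "stratifiedComparison")
}

#' @export
print.stratifiedComparison <- function(x, ...) {
  cat("Kruskal-Wallis: H =", format(x$H, digits = 4),
      ", p =", format(x$p, digits = 4), "\n")
  cat("Groups:\n")
  print(x$grouping, row.names = FALSE)
  cat("Dunn pairwise (", x$adjust, "-adjusted):\n", sep = "")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
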