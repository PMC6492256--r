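#' Pearson chi-square for a 2x2 contingency table
#'
#' Uncorrected Pearson statistic
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree of freedom, with no
#' continuity correction. Errors if any margin is zero (the statistic is
#' undefined).
#'
#' @param a,b,c,d Non-negative integer counts; rows index the grouping
#'   factor, columns the outcome. Alternatively pass a 2x2 matrix (or
#'   length-4 vector, row-major) as `a`.
#' @return List with `statistic`, `df` (always 1) and `p_value`.
#' @examples
#' chi2_2x2(7, 13, 1, 19)  # 5.625, p ~ .018
#' @export
chi2_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) {
    x <- if (is.matrix(a)) as.vector(t(a)) else as.vector(a)
    stopifnot(length(x) == 4L)
    a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  }
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  n <- sum(counts)
  if (n == 0) stop("empty table")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    stop("zero margin: the chi-square statistic is undefined for this table")
  }
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Regularization proportions by role, dyad type and round
#'
#' Proportion of irregular-cell directing trials on which the regularized
#' form was produced, with exact binomial 95% confidence intervals, per
#' director role x dyad type x round plus pooled rows (`round = "all"`).
#'
#' @param trials Trial table from [simulate_dyad()] / [simulate_exp3()] (or
#'   real trials in the same layout).
#' @return Tibble with `dyad_type`, `director_role`, `round`, `regularized`
#'   (numerator), `n_trials`, `proportion`, `ci_low`, `ci_high`. Zero
#'   irregular trials yields an empty tibble with a warning.
#' @export
regularization_summary <- function(trials) {
  irr <- trials[!is.na(trials$regularized), , drop = FALSE]
  if (nrow(irr) == 0L) {
    warning("no irregular-cell trials in input")
    return(tibble::tibble(dyad_type = character(0), director_role = character(0),
                          round = character(0), regularized = integer(0),
                          n_trials = integer(0), proportion = numeric(0),
                          ci_low = numeric(0), ci_high = numeric(0)))
  }
  irr$round <- as.character(irr$round)
  pooled <- irr
  pooled$round <- "all"
  both <- rbind(irr, pooled)
  groups <- unique(both[c("dyad_type", "director_role", "round")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- both[both$dyad_type == groups$dyad_type[i] &
                both$director_role == groups$director_role[i] &
                both$round == groups$round[i], ]
    x <- sum(g$regularized); n <- nrow(g)
    ci <- stats::binom.test(x, n)$conf.int
    tibble::tibble(dyad_type = groups$dyad_type[i],
                   director_role = groups$director_role[i],
                   round = groups$round[i], regularized = as.integer(x),
                   n_trials = as.integer(n), proportion = x / n,
                   ci_low = ci[1], ci_high = ci[2])
  })
  do.call(rbind, out)
}

#' Communicative success proportions
#'
#' Proportion of correctly matched directing trials per round x dyad type x
#' item type (regular vs. irregular target cell), plus pooled rows.
#'
#' @param trials Trial table carrying `matched_correctly`.
#' @return Tibble with `dyad_type`, `item_type`, `round`, `matched`,
#'   `n_trials`, `proportion`.
#' @export
communicative_success_summary <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0L) stop("empty trial input")
  trials$round <- as.character(trials$round)
  pooled <- trials
  pooled$round <- "all"
  both <- rbind(trials, pooled)
  groups <- unique(both[c("dyad_type", "item_type", "round")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- both[both$dyad_type == groups$dyad_type[i] &
                both$item_type == groups$item_type[i] &
                both$round == groups$round[i], ]
    tibble::tibble(dyad_type = groups$dyad_type[i],
                   item_type = groups$item_type[i], round = groups$round[i],
                   matched = sum(g$matched_correctly),
                   n_trials = as.integer(nrow(g)),
                   proportion = mean(g$matched_correctly))
  })
  do.call(rbind, out)
}
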