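#' Encode study covariates to the numeric coding of the analysis
#'
#' Maps raw study labels to the numeric covariates used by the models:
#' steam intensity `low/medium/high -> 1/2/3` (numbers 1-3 pass through);
#' time `"before" -> -1`, `"after" -> 0`, `"30 min" -> 0.5`, `"N h" -> N`
#' (numbers pass through); anatomical position is a fraction in `[0, 1]`
#' with 0 at the distal end (carina) and 1 at the proximal end (larynx).
#'
#' @param records Data frame with columns `intensity`, `time_label` (or
#'   `time`), `position`, plus any others (carried through).
#' @return The input with numeric columns `intensity`, `time`, `position`.
#' @examples
#' encode_covariates(data.frame(intensity = "medium", time_label = "2 h",
#'                              position = 0.7))
#' @export
encode_covariates <- function(records) {
  stopifnot(is.data.frame(records))
  out <- records
  out$intensity <- vapply(records$intensity, encode_intensity, numeric(1))
  tl <- if ("time_label" %in% names(records)) records$time_label
        else records$time
  if (is.null(tl)) stop("encode_covariates: no time_label/time column")
  out$time <- vapply(tl, encode_time, numeric(1))
  out$time_label <- NULL
  pos <- records$position
  if (is.null(pos)) stop("encode_covariates: no position column")
  pos <- as.numeric(pos)
  if (any(is.na(pos) | pos < 0 | pos > 1))
    stop("encode_covariates: position must be a fraction in [0, 1]; got: ",
         paste(records$position[is.na(pos) | pos < 0 | pos > 1],
               collapse = ", "))
  out$position <- pos
  out
}

encode_intensity <- function(x) {
  if (is.numeric(x) && x %in% 1:3) return(as.numeric(x))
  key <- tolower(trimws(as.character(x)))
  map <- c(low = 1, medium = 2, high = 3, "1" = 1, "2" = 2, "3" = 3)
  if (!key %in% names(map))
    stop("encode_covariates: unknown intensity label: '", x, "'")
  unname(map[key])
}

encode_time <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  key <- tolower(trimws(as.character(x)))
  if (key %in% c("before", "before treatment", "pre", "pre-treatment"))
    return(-1)
  if (key %in% c("after", "after injury", "after treatment", "post", "0 h"))
    return(0)
  if (grepl("^30 ?min$", key)) return(0.5)
  m <- regmatches(key, regexec("^([0-9]+(\\.[0-9]+)?) ?h(ours?)?$", key))[[1]]
  if (length(m)) return(as.numeric(m[2]))
  stop("encode_covariates: unknown time label: '", x, "'")
}

# terms like "intensity:time"; variables of a term
.term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# does term u contain term t (strictly)?
.term_contains <- function(u, t) {
  vu <- .term_vars(u); vt <- .term_vars(t)
  length(vu) > length(vt) && all(vt %in% vu)
}

.check_design <- function(df, vars, n_terms) {
  for (v in vars) {
    x <- df[[v]]
    if (is.null(x)) stop("model term variable not in table: ", v)
    if (length(unique(x)) < 2)
      stop("constant predictor: '", v, "' has a single distinct value")
  }
  if (nrow(df) <= n_terms + 1)
    stop("too few rows (", nrow(df), ") for ", n_terms, " model terms")
}

#' Multiway ANOVA of nCsC on coded study covariates
#'
#' Fits a linear model of the response on the numerically coded covariates
#' (treated as continuous, matching the numeric coding of intensity, time
#' and position) together with requested interaction products, and reports
#' an F statistic and p-value per term. With `ss_type = 2` (default,
#' appropriate for unbalanced designs) each term is tested against the model
#' containing all terms that do not include it; `ss_type = 1` gives
#' sequential sums of squares in the order given.
#'
#' @param table Data frame holding the response and covariate columns.
#' @param terms Character vector of model terms; interactions as
#'   `"a:b"`/`"a:b:c"` products of coded covariates.
#' @param response Response column name.
#' @param ss_type 1 or 2.
#' @return Data frame `term, df, statistic, p_value` of class
#'   `aoctel_model_report` (attribute `model` holds the full `lm` fit).
#' @examples
#' d <- data.frame(intensity = rep(1:3, 8), time = rep(c(-1, 0, 2, 4), 6),
#'                 position = runif(24), ncsc = rnorm(24, 1))
#' anova_ncsc(d, c("intensity", "time", "position"))
#' @export
anova_ncsc <- function(table, terms = c("intensity", "time", "position",
                                        "intensity:time",
                                        "intensity:position",
                                        "time:position",
                                        "intensity:time:position"),
                       response = "ncsc", ss_type = 2) {
  stopifnot(is.data.frame(table), length(terms) >= 1, ss_type %in% 1:2)
  vars <- unique(unlist(lapply(terms, .term_vars)))
  .check_design(table, c(response, vars), length(terms))
  full_fml <- stats::reformulate(terms, response = response)
  full <- stats::lm(full_fml, data = table)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("anova_ncsc: rank-deficient design; aliased terms: ",
         paste(bad, collapse = ", "))
  }
  if (ss_type == 1) {
    a <- stats::anova(full)
    keep <- rownames(a) != "Residuals"
    rep <- data.frame(term = rownames(a)[keep], df = a$Df[keep],
                      statistic = a$`F value`[keep],
                      p_value = a$`Pr(>F)`[keep])
  } else {
    rows <- lapply(terms, function(tt) {
      others <- terms[terms != tt & !vapply(terms, .term_contains, logical(1),
                                            t = tt)]
      base_fml <- if (length(others))
        stats::reformulate(others, response = response)
      else stats::as.formula(paste(response, "~ 1"))
      m0 <- stats::lm(base_fml, data = table)
      m1 <- stats::lm(stats::reformulate(c(others, tt), response = response),
                      data = table)
      a <- stats::anova(m0, m1)
      data.frame(term = tt, df = a$Df[2], statistic = a$F[2],
                 p_value = a$`Pr(>F)`[2])
    })
    rep <- do.call(rbind, rows)
  }
  rownames(rep) <- NULL
  attr(rep, "model") <- full
  class(rep) <- c("aoctel_model_report", class(rep))
  rep
}

#' Ordinary least-squares regression with tidy output
#'
#' Fits `response ~ predictors` by OLS on the coded numeric covariates and
#' reports coefficient, standard error and p-value per predictor (plus the
#' intercept). Used both for nCsC on intensity/time/position and for the
#' histologic injury grade on intensity/position.
#'
#' @param table Data frame.
#' @param response Response column name.
#' @param predictors Character vector of predictor columns.
#' @return Data frame `term, coef, se, p_value` of class
#'   `aoctel_model_report` (attribute `model` holds the `lm` fit).
#' @examples
#' d <- data.frame(position = seq(0, 1, length.out = 20))
#' d$y <- 2 - 0.5 * d$position
#' regress(d, "y", "position")
#' @export
regress <- function(table, response, predictors) {
  stopifnot(is.data.frame(table), length(predictors) >= 1)
  vars <- unique(unlist(lapply(predictors, .term_vars)))
  .check_design(table, c(response, vars), length(predictors))
  fit <- stats::lm(stats::reformulate(predictors, response = response),
                   data = table)
  sm <- summary(fit)$coefficients
  rep <- data.frame(term = rownames(sm), coef = sm[, 1], se = sm[, 2],
                    p_value = sm[, 4])
  rownames(rep) <- NULL
  attr(rep, "model") <- fit
  class(rep) <- c("aoctel_model_report", class(rep))
  rep
}

#' @export
print.aoctel_model_report <- function(x, ...) {
  cat("model report:\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
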