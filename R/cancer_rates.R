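#' Cancer sites modelled by the package
#'
#' The solid-cancer sites plus leukemia (excluding chronic lymphocytic
#' leukemia). `breast` and `ovary` are female-only; `prostate` is male-only.
#' Uterine cancer is deliberately excluded: its radiogenic risk estimates are
#' small and it carries no risk-model entry.
#'
#' @param sex Optionally restrict to the sites applicable to one sex.
#' @return Character vector of tissue labels.
#' @export
cancer_tissues <- function(sex = NULL) {
  solid <- c("lung", "stomach", "colon", "liver", "bladder", "esophagus",
             "brain", "pancreas", "breast", "ovary", "prostate", "thyroid",
             "other")
  tissues <- c(solid, "leukemia")
  if (is.null(sex)) return(tissues)
  sex <- match.arg(sex, c("female", "male"))
  drop <- if (sex == "female") "prostate" else c("breast", "ovary")
  setdiff(tissues, drop)
}

#' Tissues restricted to a single sex
#' @return Named character vector mapping tissue to the sex it applies to.
#' @export
sex_specific_tissues <- function() {
  c(breast = "female", ovary = "female", prostate = "male")
}

#' Construct a table of background cancer incidence and mortality rates
#'
#' Holds age-specific background incidence \eqn{\lambda_{0IT}(a)} and
#' mortality \eqn{\lambda_{0MT}(a)} per 100,000 person-years for each tissue,
#' on integer ages 0..100.
#'
#' @param data A data frame with columns `age`, `tissue`, `incidence`,
#'   `mortality` (rates per 100,000 person-years), one row per age x tissue.
#' @param population Population label.
#' @param sex `"female"` or `"male"`; sex-specific tissues are only accepted
#'   for the matching sex.
#' @return An object of class `cancer_rate_table`.
#' @export
cancer_rate_table <- function(data, population = "unspecified",
                              sex = c("female", "male")) {
  sex <- match.arg(sex)
  need <- c("age", "tissue", "incidence", "mortality")
  if (!all(need %in% names(data))) {
    stop("rate data must have columns: ", paste(need, collapse = ", "))
  }
  data$tissue <- as.character(data$tissue)
  known <- cancer_tissues()
  bad <- setdiff(unique(data$tissue), known)
  if (length(bad) > 0) stop("unknown tissue(s): ", paste(bad, collapse = ", "))
  ss <- sex_specific_tissues()
  wrong <- intersect(unique(data$tissue), names(ss)[ss != sex])
  if (length(wrong) > 0) {
    stop("tissue(s) not applicable to sex '", sex, "': ",
         paste(wrong, collapse = ", "))
  }
  if (any(!is.finite(data$incidence)) || any(data$incidence < 0) ||
      any(!is.finite(data$mortality)) || any(data$mortality < 0)) {
    stop("rates must be finite and non-negative")
  }
  for (tis in unique(data$tissue)) {
    ages <- sort(data$age[data$tissue == tis])
    if (!identical(as.integer(ages), 0:100)) {
      stop("tissue '", tis, "' must cover ages 0..100 exactly once each")
    }
  }
  data <- data[order(data$tissue, data$age), need]
  rownames(data) <- NULL
  structure(data,
            population = population, sex = sex,
            class = c("cancer_rate_table", "data.frame"))
}

#' @export
print.cancer_rate_table <- function(x, ...) {
  cat(sprintf("Cancer rate table: %s %s, %d tissues, ages 0..100\n",
              attr(x, "population"), attr(x, "sex"),
              length(unique(x$tissue))))
  invisible(x)
}

#' Read / write cancer rate tables as delimited text
#'
#' CSV columns `age,tissue,incidence,mortality` with optional `# key: value`
#' metadata lines (`population`, `sex`).
#'
#' @param path File path.
#' @return `read_cancer_rates` returns a [cancer_rate_table()];
#'   `write_cancer_rates` returns `path` invisibly.
#' @export
read_cancer_rates <- function(path) {
  meta <- read_hash_metadata(path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cancer_rate_table(df,
                    population = meta$population %||% "unspecified",
                    sex = meta$sex %||% "female")
}

#' @rdname read_cancer_rates
#' @param rates A [cancer_rate_table()].
#' @export
write_cancer_rates <- function(rates, path) {
  stopifnot(inherits(rates, "cancer_rate_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# population: %s", attr(rates, "population")),
               sprintf("# sex: %s", attr(rates, "sex"))), con)
  df <- as.data.frame(rates)
  df$incidence <- sprintf("%.17g", df$incidence)
  df$mortality <- sprintf("%.17g", df$mortality)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Enforce consistency between background incidence and mortality
#'
#' Delay-adjusted incidence rates can fall below raw mortality rates at old
#' ages (seen e.g. for liver and brain cancers), which would make the
#' mortality-to-incidence transfer ratio exceed 1. Wherever
#' \eqn{\lambda_{0MT}(a) > \lambda_{0IT}(a)/1.1}, mortality is capped at
#' \eqn{\lambda_{0IT}(a)/1.1}, i.e. incidence is kept at least 10\% above
#' mortality. The operation is idempotent. The number of corrected cells is
#' reported via `message()` and stored in attribute `n_corrected`.
#'
#' @param rates A [cancer_rate_table()].
#' @param margin Required incidence/mortality ratio (default 1.1).
#' @return The corrected table.
#' @export
apply_mortality_correction <- function(rates, margin = 1.1) {
  stopifnot(inherits(rates, "cancer_rate_table"), margin >= 1)
  cap <- rates$incidence / margin
  hit <- rates$mortality > cap
  n <- sum(hit)
  if (n > 0) {
    rates$mortality[hit] <- cap[hit]
    message(sprintf("mortality correction applied to %d age x tissue cells", n))
  }
  attr(rates, "n_corrected") <- n
  rates
}

#' Age-adjusted rate under a standard population
#'
#' Weighted sum of age-specific rates with weights from a standard age
#' distribution, per 100,000 persons. Used to validate synthetic populations
#' against published age-adjusted incidence totals.
#'
#' @param rates A [cancer_rate_table()].
#' @param weights Standard-population weights over ages 0..100, summing to 1;
#'   defaults to [us2000_standard_weights()].
#' @param tissue Tissue label(s) to total over; defaults to all tissues in
#'   the table.
#' @param type `"incidence"` (default) or `"mortality"`.
#' @return Age-adjusted rate per 100,000.
#' @export
age_adjusted_rate <- function(rates, weights = us2000_standard_weights(),
                              tissue = NULL, type = c("incidence", "mortality")) {
  stopifnot(inherits(rates, "cancer_rate_table"))
  type <- match.arg(type)
  if (length(weights) != 101) {
    stop("weights must have one entry per age 0..100 (length 101)")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (is.null(tissue)) tissue <- unique(rates$tissue)
  miss <- setdiff(tissue, unique(rates$tissue))
  if (length(miss) > 0) stop("tissue(s) absent from table: ",
                             paste(miss, collapse = ", "))
  tot <- 0
  for (tis in tissue) {
    sub <- rates[rates$tissue == tis, ]
    sub <- sub[order(sub$age), ]
    tot <- tot + sum(weights * sub[[type]])
  }
  tot
}

#' Single-year weights approximating the US 2000 standard population
#'
#' The 19-group US 2000 standard million (ages <1, 1-4, 5-9, ..., 80-84, 85+)
#' spread uniformly over single years of age, with the open 85+ group spread
#' over ages 85..100. This is the package's default standardisation for
#' age-adjusted rates; any other weight vector over ages 0..100 may be
#' substituted.
#'
#' @return Numeric vector of length 101 summing to 1.
#' @export
us2000_standard_weights <- function() {
  std_million <- c(13818, 55317, 72533, 73032, 72169, 66478, 64529, 71044,
                   80762, 81851, 72118, 62716, 48454, 38793, 34264, 31773,
                   26999, 17842, 15508)
  sizes <- c(1, 4, rep(5, 16), 16)  # single ages per group; 85+ -> 85..100
  w <- rep(std_million / sizes, times = sizes)
  w / sum(w)
}
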