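#' Construct a population life table
#'
#' A life table holds the all-cause mortality hazard and the survival function
#' \eqn{S_0(a)} of a reference population on integer ages 0..100. Rates are
#' treated as piecewise constant over each year of age \eqn{[a, a+1)}, so that
#' \eqn{S_0(a) = \exp(-\sum_{k<a} h(k))}. Either the hazard or the survival
#' column may be supplied; the other is derived under this convention.
#'
#' @param age Integer ages; must cover 0..100 without gaps.
#' @param hazard All-cause mortality rate per person-year at each age
#'   (optional if `survival` given).
#' @param survival Probability of being alive at each age, `S0(0) = 1`
#'   (optional if `hazard` given).
#' @param population Population label (e.g. `"white"`, `"api"`).
#' @param sex `"female"` or `"male"`.
#' @return An object of class `life_table`: a data frame with columns
#'   `age`, `hazard`, `survival` and attributes `population`, `sex`.
#' @examples
#' lt <- life_table(0:100, hazard = rep(0.01, 101))
#' life_expectancy(lt)
#' @export
life_table <- function(age, hazard = NULL, survival = NULL,
                       population = "unspecified",
                       sex = c("female", "male")) {
  sex <- match.arg(sex)
  age <- as.integer(age)
  full <- 0:100
  missing_ages <- setdiff(full, age)
  if (length(missing_ages) > 0) {
    stop("life table is missing ages: ",
         paste(missing_ages[seq_len(min(10, length(missing_ages)))],
               collapse = ", "),
         if (length(missing_ages) > 10) ", ..." else "")
  }
  if (anyDuplicated(age)) stop("duplicated ages in life table")
  ord <- order(age)
  age <- age[ord]
  if (is.null(hazard) && is.null(survival)) {
    stop("one of 'hazard' or 'survival' must be supplied")
  }
  if (!is.null(hazard)) {
    hazard <- as.numeric(hazard)[ord]
    if (any(!is.finite(hazard)) || any(hazard < 0)) {
      stop("hazard must be finite and non-negative at every age")
    }
  }
  if (!is.null(survival)) {
    survival <- as.numeric(survival)[ord]
    if (abs(survival[1] - 1) > 1e-12) stop("survival at age 0 must equal 1")
    if (any(diff(survival) > 1e-15)) stop("survival must be non-increasing in age")
    if (any(survival < 0)) stop("survival must be non-negative")
  }
  if (is.null(survival)) {
    survival <- exp(-cumsum(c(0, hazard[-length(hazard)])))
  }
  if (is.null(hazard)) {
    # hazard on [a, a+1) from consecutive survival values; the hazard for the
    # final year (age 100) lies beyond the integration cutoff and is carried
    # forward from age 99.
    r <- survival[-1] / survival[-length(survival)]
    h <- ifelse(r > 0, -log(r), Inf)
    if (any(!is.finite(h))) {
      # survival hits zero: keep a large finite hazard so downstream
      # arithmetic stays defined (survival is already 0 from there on)
      h[!is.finite(h)] <- 745  # exp(-745) underflows to 0
    }
    hazard <- c(h, h[length(h)])
  }
  out <- data.frame(age = age, hazard = hazard, survival = survival)
  structure(out,
            population = population,
            sex = sex,
            class = c("life_table", "data.frame"))
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Life table: %s %s (ages 0..100)\n",
              attr(x, "population"), attr(x, "sex")))
  cat(sprintf("  life expectancy at birth: %.1f y\n", life_expectancy(x)))
  invisible(x)
}

#' Read a life table from delimited text
#'
#' Expects a CSV with a header naming `age` and at least one of `hazard`,
#' `survival`. Metadata lines of the form `# key: value` (keys `population`,
#' `sex`) may precede the header.
#'
#' @param path Path to the CSV file.
#' @return A [life_table()].
#' @export
read_life_table <- function(path) {
  meta <- read_hash_metadata(path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"age" %in% names(df)) stop("life table file must have an 'age' column")
  life_table(age = df$age,
             hazard = if ("hazard" %in% names(df)) df$hazard else NULL,
             survival = if ("survival" %in% names(df)) df$survival else NULL,
             population = meta$population %||% "unspecified",
             sex = meta$sex %||% "female")
}

#' Write a life table as delimited text
#'
#' @param table A [life_table()].
#' @param path Output path; metadata are written as `# key: value` lines
#'   before the header.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "life_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# population: %s", attr(table, "population")),
               sprintf("# sex: %s", attr(table, "sex"))), con)
  df <- as.data.frame(table)
  # full round-trip precision for the numeric columns
  df$hazard <- sprintf("%.17g", df$hazard)
  df$survival <- sprintf("%.17g", df$survival)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Life expectancy from a given age
#'
#' Expected age at death conditional on being alive at `from_age`, under the
#' piecewise-constant-hazard convention and truncation of the lifetime
#' integral at age 100: persons alive at 100 contribute no further years.
#'
#' @param table A [life_table()].
#' @param from_age Conditioning age in 0..100.
#' @return Expected age at death in years (i.e. `from_age` plus expected
#'   remaining years).
#' @export
life_expectancy <- function(table, from_age = 0) {
  stopifnot(inherits(table, "life_table"))
  if (from_age < 0 || from_age > 100) {
    stop("from_age must lie within the age grid 0..100")
  }
  a0 <- as.integer(from_age)
  h <- table$hazard
  s <- table$survival
  if (s[a0 + 1] <= 0) stop("no survivors at from_age; expectation undefined")
  idx <- (a0 + 1):100  # year intervals [a, a+1) for a = a0..99
  hh <- h[idx]
  # expected time lived within [a, a+1) given alive at a:  (1 - e^-h)/h
  w <- ifelse(hh > 0, (1 - exp(-hh)) / hh, 1)
  from_age + sum(s[idx] * w) / s[a0 + 1]
}

# internal: parse leading "# key: value" lines
read_hash_metadata <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  meta
}

`%||%` <- function(a, b) if (is.null(a)) b else a
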