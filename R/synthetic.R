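#' Default decadal age structure of the adult population
#'
#' Proportions of the over-20 population in decadal bands, shaped like a
#' middle-income country's adult age pyramid. Used by the synthetic
#' population generator.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_age_structure <- function() {
  c("20-29" = 0.26, "30-39" = 0.22, "40-49" = 0.18, "50-59" = 0.15,
    "60-69" = 0.10, "70-79" = 0.06, "80+" = 0.03)
}

# Largest-remainder apportionment of `total` over `proportions`;
# conserves the total exactly.
.apportion <- function(total, proportions) {
  raw <- total * proportions
  base <- floor(raw)
  short <- round(total - sum(base))
  if (short > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(short)]] <- base[order_rem[seq_len(short)]] + 1
  }
  base
}

#' Generate a synthetic adult population projection
#'
#' Stand-in for a national statistics office projection of the over-20
#' population: a smoothly growing total, apportioned over decadal age
#' bands by largest-remainder rounding so that age-group counts always sum
#' exactly to the annual total.
#'
#' @param base_total Over-20 population in the first year.
#' @param annual_growth Annual growth rate (e.g. 0.012 for 1.2%/year).
#' @param years Calendar years to project.
#' @param age_structure Named proportions summing to 1.
#' @param seed Unused source of randomness kept for interface uniformity;
#'   the projection is a pure function of its arguments.
#' @return Data frame with columns `year`, `age_group`, `count`.
#' @export
generate_population <- function(base_total = 33e6, annual_growth = 0.012,
                                years = 2018:2020,
                                age_structure = default_age_structure(),
                                seed = 1L) {
  stopifnot(base_total > 0, annual_growth > -1)
  if (abs(sum(age_structure) - 1) > 1e-6) {
    stop("age_structure proportions must sum to 1")
  }
  years <- as.integer(years)
  rows <- lapply(seq_along(years), function(i) {
    total <- round(base_total * (1 + annual_growth)^(i - 1))
    data.frame(year = years[i], age_group = names(age_structure),
               count = .apportion(total, age_structure),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Total over-20 population of a projection year
#'
#' @param projection A projection from [generate_population()].
#' @param year Calendar year.
#' @return Integer total.
#' @export
population_total <- function(projection, year) {
  rows <- projection$year == year
  if (!any(rows)) stop("projection does not cover year ", year)
  sum(projection$count[rows])
}

#' Generate paired age-specific prevalence tables
#'
#' Builds two age-increasing hypertension prevalence tables (old and new
#' diagnostic cut-offs) whose population-weighted overall prevalences hit
#' the requested targets exactly, with the new-cut-off proportion
#' dominating the old one in every age band. Both tables share one
#' age-gradient shape, so the ratio of prevalent counts between cut-offs
#' is constant across bands.
#'
#' @param old_overall Overall prevalence under the old cut-off (140/90).
#' @param new_overall Overall prevalence under the new cut-off (130/80);
#'   must exceed `old_overall`.
#' @param age_groups Age band labels.
#' @param weights Population proportions per band (used for the weighted
#'   overall prevalence); defaults to [default_age_structure()].
#' @param seed Unused; the tables are deterministic in their arguments.
#' @return List with `old` and `new` data frames
#'   (`age_group`, `proportion_hypertensive`).
#' @export
generate_prevalence_table <- function(old_overall, new_overall,
                                      age_groups = names(default_age_structure()),
                                      weights = default_age_structure(),
                                      seed = 1L) {
  stopifnot(old_overall > 0, new_overall < 1)
  if (new_overall < old_overall) {
    stop("new_overall must be at least old_overall")
  }
  k <- length(age_groups)
  # fixed age gradient: relative hypertension risk rises with age band
  rel <- seq(0.3, 3.4, length.out = k)^1.15
  w <- weights / sum(weights)
  base <- sum(w * rel)
  mk <- function(target) {
    p <- rel * target / base
    if (any(p >= 1)) stop("infeasible prevalence target ", target)
    data.frame(age_group = age_groups, proportion_hypertensive = p,
               stringsAsFactors = FALSE)
  }
  list(old = mk(old_overall), new = mk(new_overall))
}

#' Generate a synthetic administrative event-count series
#'
#' Stand-in for annual claims counts of a cardiovascular event (ICD-10
#' coded): a linear trend with Gaussian noise, rounded and clipped at
#' zero. Reproducible for a given seed.
#'
#' @param code ICD-10 code: `"I219"` (AMI), `"I509"` (heart failure) or
#'   `"I64"` (stroke).
#' @param base_count Count in the first year.
#' @param trend_per_year Additive annual trend.
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_years Series length (at least 3).
#' @param seed RNG seed.
#' @param start_year First calendar year.
#' @return Data frame with columns `year`, `count` and attribute
#'   `icd10_code`.
#' @export
generate_event_history <- function(code = c("I219", "I509", "I64"),
                                   base_count, trend_per_year = 0,
                                   noise_sd = 0, n_years = 8, seed = 1L,
                                   start_year = 2010L) {
  code <- match.arg(code)
  stopifnot(n_years >= 3, base_count >= 0, noise_sd >= 0)
  k <- seq_len(n_years) - 1
  noise <- withr_seed(seed, stats::rnorm(n_years, 0, noise_sd))
  counts <- pmax(0, round(base_count + trend_per_year * k + noise))
  out <- data.frame(year = as.integer(start_year + k), count = counts)
  attr(out, "icd10_code") <- code
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Read/write the synthetic-data CSV formats
#'
#' UTF-8 CSV with a header row. Column orders: population
#' `year,age_group,count`; prevalence `age_group,proportion_hypertensive`;
#' event history `year,count` (ICD-10 code in the `icd10_code` column on
#' write, restored as an attribute on read).
#'
#' @param x Object to write.
#' @param path CSV file path.
#' @return The data frame (readers) or `path`, invisibly (writers).
#' @name synthetic_csv
NULL

#' @rdname synthetic_csv
#' @export
write_population_csv <- function(x, path) {
  utils::write.csv(x[, c("year", "age_group", "count")], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname synthetic_csv
#' @export
read_population_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' @rdname synthetic_csv
#' @export
write_prevalence_csv <- function(x, path) {
  utils::write.csv(x[, c("age_group", "proportion_hypertensive")], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname synthetic_csv
#' @export
read_prevalence_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' @rdname synthetic_csv
#' @export
write_event_history_csv <- function(x, path) {
  out <- data.frame(icd10_code = attr(x, "icd10_code"), x)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname synthetic_csv
#' @export
read_event_history_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  out <- raw[, c("year", "count")]
  attr(out, "icd10_code") <- raw$icd10_code[1]
  out
}
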