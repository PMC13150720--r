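#' Construct a life table
#'
#' A life table maps integer age to the annual all-cause mortality rate
#' (events per person-year). Lookup is piecewise constant: ages between rows
#' take the rate of the highest row at or below them, ages beyond the last
#' row take the last rate, and ages below the first row take the first rate,
#' so lookup is total on all non-negative ages.
#'
#' @param age Integer ages, strictly increasing.
#' @param annual_mortality_rate Rates in `[0, 1]`, one per age.
#' @return A `data.frame` of class `life_table`.
#' @export
life_table <- function(age, annual_mortality_rate) {
  age <- as.numeric(age)
  annual_mortality_rate <- as.numeric(annual_mortality_rate)
  if (length(age) != length(annual_mortality_rate) || length(age) == 0L)
    stop("age and annual_mortality_rate must have equal positive length",
         call. = FALSE)
  if (any(diff(age) <= 0)) stop("ages must be strictly increasing", call. = FALSE)
  if (any(annual_mortality_rate < 0 | annual_mortality_rate > 1))
    stop("annual mortality rates must lie in [0, 1]", call. = FALSE)
  structure(data.frame(age = age,
                       annual_mortality_rate = annual_mortality_rate),
            class = c("life_table", "data.frame"))
}

#' Look up the annual mortality rate at an age
#'
#' @param lt A [life_table()].
#' @param age Numeric vector of non-negative ages (need not be integer).
#' @return Annual mortality rate(s), per person-year.
#' @export
lookup_mortality_rate <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  idx <- findInterval(age, lt$age)
  idx[idx < 1L] <- 1L
  lt$annual_mortality_rate[idx]
}

#' Read / write the life-table CSV
#'
#' The on-disk format is a CSV with header `age,annual_mortality_rate`.
#'
#' @param path File path.
#' @return `read_life_table()` returns a [life_table()];
#'   `write_life_table()` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("age", "annual_mortality_rate")
  if (!identical(names(df), need))
    stop("life table CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  life_table(df$age, df$annual_mortality_rate)
}

#' @rdname read_life_table
#' @param lt A [life_table()].
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert an annual event rate to a per-cycle probability
#'
#' The hazard ratio scales the rate (not the probability); the per-cycle
#' probability is then `1 - exp(-rate * hazard_ratio * cycle_length)`, the
#' standard actuarial conversion under a constant hazard within the cycle.
#'
#' @param rate Annual rate, per person-year, `>= 0`.
#' @param hazard_ratio Dimensionless multiplier on the rate, `> 0`.
#' @param cycle_length Cycle length in years, `> 0`.
#' @return Probability in `[0, 1)` of the event within one cycle.
#' @export
#' @examples
#' annual_rate_to_cycle_prob(0.02, 2, 0.25)  # 1 - exp(-0.01)
annual_rate_to_cycle_prob <- function(rate, hazard_ratio, cycle_length) {
  if (any(rate < 0)) stop("rate must be non-negative", call. = FALSE)
  if (any(hazard_ratio <= 0)) stop("hazard_ratio must be positive", call. = FALSE)
  if (any(cycle_length <= 0)) stop("cycle_length must be positive", call. = FALSE)
  1 - exp(-rate * hazard_ratio * cycle_length)
}

#' Per-cycle discount factor
#'
#' Discrete discounting of an annual rate applied at cycle resolution:
#' cycle `t` is discounted by `(1 + r)^(-t * cycle_length)`, so cycle 0 has
#' factor 1 and a full year of cycles compounds to `1 / (1 + r)`.
#'
#' @param cycle_index Non-negative integer cycle index (vectorized).
#' @param r Annual discount rate as a fraction, `0 <= r < 1`.
#' @param cycle_length Cycle length in years.
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(cycle_index, r, cycle_length) {
  if (any(cycle_index < 0)) stop("cycle_index must be non-negative", call. = FALSE)
  if (r < 0 || r >= 1) stop("r must be in [0, 1)", call. = FALSE)
  (1 + r)^(-cycle_index * cycle_length)
}
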