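#' Life tables: construction, I/O and monthly mortality lookup
#'
#' A `tka_life_table` is a data frame with integer column `age` (contiguous
#' years) and numeric column `qx`, the annual probability of death at that
#' age.  It is the model's only source of background (all-cause) mortality.
#' Ages beyond the table maximum are treated as certain death (`qx = 1`).
#'
#' @param age integer vector of contiguous ages (years).
#' @param qx annual death probabilities, same length as `age`.
#' @return A validated `tka_life_table` data frame.
#' @examples
#' life_table(age = 60:61, qx = c(0.01, 1))
#' @export
life_table <- function(age, qx) {
  lt <- data.frame(age = as.integer(age), qx = as.numeric(qx))
  validate_life_table(lt)
}

#' @rdname life_table
#' @param lt a candidate life table data frame.
#' @export
validate_life_table <- function(lt) {
  stopifnot(is.data.frame(lt), all(c("age", "qx") %in% names(lt)))
  lt <- lt[order(lt$age), c("age", "qx")]
  if (nrow(lt) < 1) stop("life table is empty", call. = FALSE)
  if (anyNA(lt$age) || anyNA(lt$qx))
    stop("life table contains missing values", call. = FALSE)
  if (any(diff(lt$age) != 1))
    stop("life table ages must be contiguous integers; gap after age ",
         lt$age[which(diff(lt$age) != 1)[1]], call. = FALSE)
  if (any(lt$qx < 0 | lt$qx > 1))
    stop("life table qx outside [0, 1] at age ",
         lt$age[which(lt$qx < 0 | lt$qx > 1)[1]], call. = FALSE)
  rownames(lt) <- NULL
  class(lt) <- c("tka_life_table", "data.frame")
  lt
}

#' Read / write a life table as CSV
#'
#' The CSV format is two columns with header `age,qx`, one row per integer
#' age.
#'
#' @param path CSV file path.
#' @return `read_life_table`: a validated `tka_life_table`;
#'   `write_life_table`: `path`, invisibly.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path))
    stop("life table file not found: ", path, call. = FALSE)
  lt <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(lt)))
    stop("life table CSV must have header columns 'age' and 'qx': ", path,
         call. = FALSE)
  lt <- validate_life_table(lt)
  message("read life table ", path, ": ", nrow(lt), " ages (",
          min(lt$age), "-", max(lt$age), ")")
  lt
}

#' @rdname read_life_table
#' @param lt a `tka_life_table`.
#' @export
write_life_table <- function(lt, path) {
  lt <- validate_life_table(lt)
  utils::write.csv(lt[, c("age", "qx")], path, row.names = FALSE)
  invisible(path)
}

#' The bundled synthetic US-2009-style life table
#'
#' An all-sex life table generated with [gompertz_life_table()] at its
#' default calibration (life expectancy at age 60 of about 22.6 years,
#' matching a US 2009 all-sex period table to within about a year).  It is
#' synthetic: a two-parameter Gompertz hazard, not a copy of any national
#' table, so childhood and young-adult mortality are unrealistically low;
#' that region is irrelevant to a cohort entering at age 60.
#'
#' @return A `tka_life_table` covering ages 0--110.
#' @export
bundled_life_table <- function() {
  path <- system.file("extdata", "lifetable_us2009_style_synthetic.csv",
                      package = "tkawait", mustWork = TRUE)
  suppressMessages(read_life_table(path))
}

#' Monthly background mortality at a given (possibly fractional) age
#'
#' Looks up the annual death probability at `floor(age_years)` and converts
#' it to a monthly probability with [annual_to_monthly_prob()]; the result
#' is therefore piecewise constant within each integer year of age.  Ages
#' above the table maximum return 1 (forced absorption).
#'
#' @param lt a `tka_life_table`.
#' @param age_years age in years; must not be below the table minimum.
#' @return Monthly probability of death.
#' @export
monthly_mortality <- function(lt, age_years) {
  a <- floor(age_years)
  if (any(a < lt$age[1]))
    stop("age ", min(age_years), " below life table minimum ", lt$age[1],
         call. = FALSE)
  q <- ifelse(a > lt$age[nrow(lt)], 1, lt$qx[pmin(a - lt$age[1] + 1, nrow(lt))])
  annual_to_monthly_prob(q)
}
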