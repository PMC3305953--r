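#' Synthetic Gompertz life table
#'
#' Builds an all-cause (other-cause) mortality life table with annual death
#' probability \eqn{q(a) = 1 - \exp(-\alpha e^{\beta a})}, clipped to [0, 1],
#' with \eqn{q(100) = 1} so the model cohort is fully absorbed by age 100.
#' The defaults emulate the scale of a modern western-European national life
#' table (life expectancy in the late 70s).
#'
#' @param a Gompertz baseline hazard (default 2.2e-5).
#' @param b Gompertz age slope per year (default 0.097).
#' @param min_age,max_age integer age range covered (defaults 0 and 100).
#' @return A \code{life_table}: data frame with columns \code{age} and
#'   \code{q_other}.
#' @export
generate_life_table <- function(a = 2.2e-5, b = 0.097,
                                min_age = 0L, max_age = 100L) {
  if (a <= 0 || b <= 0) stop("Gompertz hazard parameters must be positive")
  age <- seq.int(min_age, max_age)
  q <- 1 - exp(-a * exp(b * age))
  q <- pmin(pmax(q, 0), 1)
  q[age >= 100] <- 1
  structure(data.frame(age = as.integer(age), q_other = q),
            class = c("life_table", "data.frame"))
}

#' @rdname generate_life_table
#' @param life_table a life-table data frame.
#' @param age integer age(s) to look up.
#' @return \code{q_other_at()} returns the annual other-cause death
#'   probability at \code{age}.
#' @export
q_other_at <- function(life_table, age) {
  m <- match(as.integer(age), life_table$age)
  if (anyNA(m)) stop("life table does not cover age(s) ", paste(age[is.na(m)], collapse = ", "))
  life_table$q_other[m]
}

#' Read or write a life table as CSV (\code{age,q_other})
#'
#' @param path file path.
#' @return \code{read_life_table()} returns a validated \code{life_table}.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  if (!all(c("age", "q_other") %in% names(lt))) {
    stop("life table CSV must have columns 'age' and 'q_other'")
  }
  lt$age <- as.integer(lt$age)
  if (any(lt$q_other < 0 | lt$q_other > 1)) stop("q_other outside [0,1]")
  structure(lt[, c("age", "q_other")], class = c("life_table", "data.frame"))
}

#' @rdname read_life_table
#' @param life_table the table to write.
#' @export
write_life_table <- function(life_table, path) {
  d <- as.data.frame(life_table)[, c("age", "q_other")]
  d$q_other <- sprintf("%.17g", d$q_other)  # bit-exact round trip
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
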