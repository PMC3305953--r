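#' Health-state space of the natural-history model
#'
#' Enumerates the model's health states in a fixed, deterministic order.
#' One cell per combination of lesion compartment, anatomical location and
#' (for cancers) clinical status:
#' \itemize{
#'   \item \code{normal} — normal colorectal epithelium;
#'   \item low-risk (<10 mm) and higher-risk (>=10 mm) adenomas, each split
#'     distal/proximal;
#'   \item pre-clinical (undiagnosed) cancer, AJCC stages I--IV, split
#'     distal/proximal;
#'   \item clinical (diagnosed) cancer, stages I--IV;
#'   \item two post-polypectomy surveillance states (intermediate- and
#'     high-risk findings), used only when a screening overlay is active;
#'   \item three absorbing death states: colorectal cancer, endoscopic
#'     perforation, other causes.
#' }
#'
#' @return A data frame with one row per state and columns \code{name},
#'   \code{compartment}, \code{location} (\code{"distal"}, \code{"proximal"}
#'   or \code{"none"}), \code{stage} (\code{NA} or 1--4), and logical flags
#'   \code{alive} and \code{prediagnosis}.
#' @export
build_state_space <- function() {
  loc2 <- c("distal", "proximal")
  rows <- list(
    data.frame(compartment = "normal", location = "none", stage = NA_integer_)
  )
  for (risk in c("adenoma_low", "adenoma_high")) {
    rows[[length(rows) + 1L]] <-
      data.frame(compartment = risk, location = loc2, stage = NA_integer_)
  }
  for (loc in loc2) {
    rows[[length(rows) + 1L]] <-
      data.frame(compartment = paste0("crc_preclin_", c("I", "II", "III", "IV")),
                 location = loc, stage = 1:4)
  }
  rows[[length(rows) + 1L]] <-
    data.frame(compartment = paste0("crc_clinical_", c("I", "II", "III", "IV")),
               location = "none", stage = 1:4)
  rows[[length(rows) + 1L]] <-
    data.frame(compartment = c("surveillance_int", "surveillance_high"),
               location = "none", stage = NA_integer_)
  rows[[length(rows) + 1L]] <-
    data.frame(compartment = c("dead_crc", "dead_perforation", "dead_other"),
               location = "none", stage = NA_integer_)
  ss <- do.call(rbind, rows)
  ss$name <- ifelse(ss$location == "none", ss$compartment,
                    paste(ss$compartment, ss$location, sep = "/"))
  ss$alive <- !startsWith(ss$compartment, "dead")
  ss$prediagnosis <- ss$alive &
    !startsWith(ss$compartment, "crc_clinical") &
    !startsWith(ss$compartment, "surveillance")
  rownames(ss) <- NULL
  ss[, c("name", "compartment", "location", "stage", "alive", "prediagnosis")]
}

# cached index helpers over the fixed state ordering
.si_cache <- new.env(parent = emptyenv())
state_index <- function() {
  if (!is.null(.si_cache$si)) return(.si_cache$si)
  .si_cache$si <- build_state_index()
  .si_cache$si
}

build_state_index <- function() {
  ss <- build_state_space()
  n <- nrow(ss)
  idx <- seq_len(n)
  names(idx) <- ss$name
  list(
    ss = ss, n = n, idx = idx,
    normal = idx[["normal"]],
    ad_low = unname(idx[c("adenoma_low/distal", "adenoma_low/proximal")]),
    ad_high = unname(idx[c("adenoma_high/distal", "adenoma_high/proximal")]),
    preclin = matrix(unname(idx[paste0("crc_preclin_", rep(c("I", "II", "III", "IV"), 2),
                                       "/", rep(c("distal", "proximal"), each = 4))]),
                     nrow = 4, dimnames = list(c("I", "II", "III", "IV"),
                                               c("distal", "proximal"))),
    clinical = unname(idx[paste0("crc_clinical_", c("I", "II", "III", "IV"))]),
    surv = unname(idx[c("surveillance_int", "surveillance_high")]),
    dead_crc = idx[["dead_crc"]],
    dead_perf = idx[["dead_perforation"]],
    dead_other = idx[["dead_other"]],
    dead = unname(idx[c("dead_crc", "dead_perforation", "dead_other")]),
    live = unname(idx[ss$alive]),
    prediag = unname(idx[ss$prediagnosis])
  )
}

#' Initial cohort state
#'
#' The cohort enters the model disease-free: all mass in the \code{normal}
#' state (pre-clinical cancer and adenoma prevalence zero at entry).
#'
#' @param age entry age in years (default 30).
#' @return A \code{cohort_state}: list with \code{age} and a named
#'   \code{occupancy} vector over the full state space summing to 1.
#' @export
initial_cohort <- function(age = 30L) {
  si <- state_index()
  occ <- stats::setNames(numeric(si$n), si$ss$name)
  occ[si$normal] <- 1
  structure(list(age = as.integer(age), occupancy = occ),
            class = "cohort_state")
}

#' Advance the cohort by one annual Markov cycle
#'
#' @param cohort a \code{cohort_state}.
#' @param matrix row-stochastic transition matrix built for \code{cohort$age}.
#' @return The cohort one year older, occupancy post-multiplied by the matrix.
#' @export
advance_cycle <- function(cohort, matrix) {
  occ <- cohort$occupancy
  if (!is.matrix(matrix) || nrow(matrix) != length(occ) ||
      ncol(matrix) != length(occ)) {
    stop("transition matrix dimensions do not match the state space")
  }
  new_occ <- as.vector(occ %*% matrix)
  names(new_occ) <- names(occ)
  structure(list(age = cohort$age + 1L, occupancy = new_occ),
            class = "cohort_state")
}
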