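#' State space of the cohort model
#'
#' The model follows the adult population through ten states: eight alive
#' states formed by crossing cardiovascular disease status (no CVD / CVD)
#' with four severity levels (unimpaired, cognitive impairment, moderate to
#' severe disability, dementia), plus two absorbing death states (CVD and
#' non-CVD causes).  Dementia is treated as the most severe level because it
#' is defined as cognitive impairment coexisting with disability.
#'
#' Permitted one-year movements:
#' * within each CVD layer: unimpaired -> cognitive impairment or
#'   disability; cognitive impairment -> dementia or disability;
#'   disability -> dementia or back to unimpaired (recovery);
#'   no recovery from dementia;
#' * no-CVD -> CVD at the same severity level (CVD incidence); CVD is not
#'   reversible;
#' * every alive state -> either death state.
#'
#' @return `bam_states()` returns the character vector of the ten state
#'   labels, in matrix order.
#' @export
bam_states <- function() {
  c("free", "cvd", "ci", "cvd_ci", "dis", "cvd_dis", "dem", "cvd_dem",
    "death_cvd", "death_noncvd")
}

# index helpers (fixed order, used throughout the package)
.S <- c(free = 1L, cvd = 2L, ci = 3L, cvd_ci = 4L, dis = 5L, cvd_dis = 6L,
        dem = 7L, cvd_dem = 8L, death_cvd = 9L, death_noncvd = 10L)
.ALIVE <- 1:8
.DEAD <- 9:10
.DISABILITY_BEARING <- c(5L, 6L, 7L, 8L)  # dis, cvd_dis, dem, cvd_dem

#' @rdname bam_states
#' @return `bam_alive_states()` returns the labels of the eight alive states.
#' @export
bam_alive_states <- function() bam_states()[.ALIVE]

#' Structurally permitted transitions
#'
#' Returns a 10 x 10 logical matrix: `TRUE` where a one-year movement from
#' the row state to the column state is structurally possible (diagonal
#' included; death rows permit only the diagonal).
#'
#' @return logical matrix with state-labelled dimnames.
#' @export
bam_transition_structure <- function() {
  s <- .S
  M <- matrix(FALSE, 10, 10, dimnames = list(bam_states(), bam_states()))
  diag(M) <- TRUE
  # severity progression within each layer
  M[s["free"], c(s["ci"], s["dis"])] <- TRUE
  M[s["ci"], c(s["dem"], s["dis"])] <- TRUE
  M[s["dis"], c(s["dem"], s["free"])] <- TRUE
  M[s["cvd"], c(s["cvd_ci"], s["cvd_dis"])] <- TRUE
  M[s["cvd_ci"], c(s["cvd_dem"], s["cvd_dis"])] <- TRUE
  M[s["cvd_dis"], c(s["cvd_dem"], s["cvd"])] <- TRUE
  # CVD incidence at any severity
  M[s["free"], s["cvd"]] <- TRUE
  M[s["ci"], s["cvd_ci"]] <- TRUE
  M[s["dis"], s["cvd_dis"]] <- TRUE
  M[s["dem"], s["cvd_dem"]] <- TRUE
  # death from every alive state
  M[.ALIVE, .DEAD] <- TRUE
  M
}

#' Transition families affected by diabetes
#'
#' Six families of transition probabilities carry diabetes relative risks:
#' CVD incidence, cognitive-decline incidence (entry into cognitive
#' impairment and progression into dementia), disability incidence,
#' recovery from disability, CVD death and non-CVD death.  Each family maps
#' to a set of cells of the transition matrix.
#'
#' @return named list; each element a two-column integer matrix of
#'   (from, to) state indices.
#' @export
bam_transition_families <- function() {
  s <- .S
  cells <- function(...) {
    m <- matrix(unlist(list(...)), ncol = 2, byrow = TRUE)
    storage.mode(m) <- "integer"
    colnames(m) <- c("from", "to")
    m
  }
  list(
    cvd_incidence = cells(c(s["free"], s["cvd"]), c(s["ci"], s["cvd_ci"]),
                          c(s["dis"], s["cvd_dis"]), c(s["dem"], s["cvd_dem"])),
    cognitive_incidence = cells(c(s["free"], s["ci"]), c(s["cvd"], s["cvd_ci"]),
                                c(s["ci"], s["dem"]), c(s["cvd_ci"], s["cvd_dem"]),
                                c(s["dis"], s["dem"]), c(s["cvd_dis"], s["cvd_dem"])),
    disability_incidence = cells(c(s["free"], s["dis"]), c(s["ci"], s["dis"]),
                                 c(s["cvd"], s["cvd_dis"]), c(s["cvd_ci"], s["cvd_dis"])),
    disability_recovery = cells(c(s["dis"], s["free"]), c(s["cvd_dis"], s["cvd"])),
    cvd_death = cbind(from = .ALIVE, to = rep(s[["death_cvd"]], 8L)),
    noncvd_death = cbind(from = .ALIVE, to = rep(s[["death_noncvd"]], 8L))
  )
}

# --- age band helpers -------------------------------------------------------

#' Age band utilities
#'
#' The mortality series is stratified by 5-year age band (35-39 ... 90-94,
#' 95+) and the diabetes duration distribution by 10-year band
#' (35-44 ... 75-84, 85+).  These helpers return the band labels and map
#' single years of age onto them.
#'
#' @param age integer vector of ages (35-100).
#' @return labels, or for the `band_of` helpers the band label of each age.
#' @export
age_bands_5y <- function() {
  c(paste(seq(35, 90, 5), seq(39, 94, 5), sep = "-"), "95+")
}

#' @rdname age_bands_5y
#' @export
age_bands_10y <- function() {
  c(paste(seq(35, 75, 10), seq(44, 84, 10), sep = "-"), "85+")
}

#' @rdname age_bands_5y
#' @export
band5_of_age <- function(age) {
  stopifnot(all(age >= 35))
  idx <- pmin((age - 35) %/% 5 + 1L, 13L)
  age_bands_5y()[idx]
}

#' @rdname age_bands_5y
#' @export
band10_of_age <- function(age) {
  stopifnot(all(age >= 35))
  idx <- pmin((age - 35) %/% 10 + 1L, 6L)
  age_bands_10y()[idx]
}

# midpoint of a 5y band (95+ treated as 97)
.band5_midpoint <- function(band) {
  m <- c(seq(37, 92, 5), 97)
  names(m) <- age_bands_5y()
  unname(m[band])
}
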