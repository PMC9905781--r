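#' Sleep stage vocabulary
#'
#' The five AASM sleep stages used throughout the package, in the fixed
#' column order of every hypnodensity matrix: wake (`W`), NREM stages
#' `N1`--`N3`, and REM (`R`). The stage set is closed: inputs carrying any
#' other code must be mapped through a dialect (see [stage_dialects()]) or
#' they are rejected.
#'
#' @return Character vector of length 5: `c("W","N1","N2","N3","R")`.
#' @export
sleep_stages <- function() c("W", "N1", "N2", "N3", "R")

#' Deterministic stage priority used for tie-breaking
#'
#' When an epoch's maximal stage probability (or vote count) is shared by
#' several stages, ties are broken by a fixed priority order. The default
#' prefers deeper / NREM-specific stages: `N3 > N2 > N1 > R > W`. The order
#' is configurable wherever it is used; any permutation of the five stages
#' is accepted.
#'
#' @return Character vector of the five stages in decreasing priority.
#' @export
stage_priority <- function() c("N3", "N2", "N1", "R", "W")

# integer codes 1..5 in sleep_stages() order; internal workhorse encoding
stage_index <- function(x) {
  i <- match(x, sleep_stages())
  if (anyNA(i)) {
    bad <- unique(x[is.na(i)])
    stop("unknown sleep stage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  i
}

check_priority <- function(priority) {
  if (!setequal(priority, sleep_stages()) || length(priority) != 5L)
    stop("`priority` must be a permutation of the five stages", call. = FALSE)
  priority
}

# rank[s] = position of stage s (index 1..5) in the priority order;
# lower rank wins ties
priority_rank <- function(priority = stage_priority()) {
  check_priority(priority)
  match(sleep_stages(), priority)
}

#' Built-in stage code dialects
#'
#' Dialects map external stage codes onto the five-stage vocabulary.
#' Two are built in:
#' \describe{
#'   \item{`aasm`}{identity mapping of the textual codes `W,N1,N2,N3,R`.}
#'   \item{`numeric`}{`0=W, 1=N1, 2=N2, 3=N3, 5=R` (the common scored-file
#'     convention in which 4 was retired with stage S4).}
#' }
#' Each dialect is a named character vector (external code -> stage) and is
#' a bijection on its declared code set, so files written by the package can
#' be read back losslessly.
#'
#' @return Named list of named character vectors.
#' @export
stage_dialects <- function() {
  list(
    aasm    = c(W = "W", N1 = "N1", N2 = "N2", N3 = "N3", R = "R"),
    numeric = c(`0` = "W", `1` = "N1", `2` = "N2", `3` = "N3", `5` = "R")
  )
}

resolve_dialect <- function(dialect) {
  if (is.character(dialect) && length(dialect) == 1L) {
    d <- stage_dialects()[[dialect]]
    if (is.null(d)) stop("unknown dialect: ", dialect, call. = FALSE)
    return(d)
  }
  if (is.character(dialect) && !is.null(names(dialect))) {
    if (!all(dialect %in% sleep_stages()))
      stop("custom dialect maps onto codes outside the five-stage set",
           call. = FALSE)
    if (anyDuplicated(dialect) || anyDuplicated(names(dialect)))
      stop("custom dialect must be a bijection on its code set", call. = FALSE)
    return(dialect)
  }
  stop("`dialect` must be a built-in dialect name or a named character vector",
       call. = FALSE)
}

#' Map external stage codes to the five-stage vocabulary
#'
#' @param codes Character vector of external codes (numeric codes are
#'   accepted and coerced to character).
#' @param dialect Dialect name (see [stage_dialects()]) or a named character
#'   vector mapping external codes to stages.
#' @return Character vector of stage labels.
#' @export
map_stage_codes <- function(codes, dialect = "aasm") {
  d <- resolve_dialect(dialect)
  codes <- trimws(as.character(codes))
  mapped <- unname(d[codes])
  if (anyNA(mapped)) {
    row <- which(is.na(mapped))[1L]
    stop(sprintf("unmapped stage code \"%s\" at row %d", codes[row], row),
         call. = FALSE)
  }
  mapped
}
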