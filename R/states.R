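# MSAP methylation states and the dual-digest band code.
#
# Each CCGG locus is assayed in two digests: EcoRI+HpaII ("H" lane) and
# EcoRI+MspI ("M" lane).  The joint presence/absence pattern encodes the
# cytosine methylation state of the site:
#
#   (H=1, M=1) -> type I    unmethylated
#   (H=1, M=0) -> type II   CHG (hemi)methylation
#   (H=0, M=1) -> type III  CG (internal cytosine) methylation
#   (H=0, M=0) -> type IV   CG/CHG methylation (no bands)

#' The four MSAP methylation states
#'
#' Character codes used throughout the package, in the conventional order
#' `I` (unmethylated), `II` (CHG methylation), `III` (CG methylation),
#' `IV` (CG/CHG methylation).
#' @export
MSAP_STATES <- c("I", "II", "III", "IV")

#' The four transition classes
#'
#' Classes for a reference-state to sample-state change at one locus:
#' `NO_CHANGE`, `DEMETHYLATION` (toward the unmethylated state),
#' `METHYLATION` (away from it), and `INTERCHANGE` (CHG <-> CG, the two
#' transitions that cannot be ordered as a gain or loss).
#' @export
TRANSITION_CLASSES <- c("NO_CHANGE", "DEMETHYLATION", "METHYLATION",
                        "INTERCHANGE")

# Methylation "load" used to order states: I < {II, III} < IV.
# II and III are incomparable (different contexts, same single-context load).
.state_level <- c(I = 0L, II = 1L, III = 1L, IV = 2L)

#' Classify a dual-digest band call into a methylation state
#'
#' Maps the (HpaII-lane, MspI-lane) presence pair of one locus to its MSAP
#' methylation state.  Vectorised; an unscored call (`NA` in either lane)
#' yields `NA`.
#'
#' @param h presence (1) / absence (0) in the EcoRI+HpaII digest; `NA` for
#'   unscored.
#' @param m presence/absence in the EcoRI+MspI digest.
#' @return character vector over [MSAP_STATES], `NA` where unscored.
#' @examples
#' msap_state(c(1, 1, 0, 0), c(1, 0, 1, 0))  # "I" "II" "III" "IV"
#' @export
msap_state <- function(h, m) {
  if (length(h) != length(m))
    stop("`h` and `m` must have equal length")
  h <- .check_binary(h, "h")
  m <- .check_binary(m, "m")
  idx <- 1L + (1L - h) * 2L + (1L - m)  # (1,1)->1 (1,0)->2 (0,1)->3 (0,0)->4
  out <- MSAP_STATES[idx]
  out[is.na(h) | is.na(m)] <- NA_character_
  out
}

.check_binary <- function(x, what) {
  x <- suppressWarnings(as.integer(x))
  bad <- !is.na(x) & !(x %in% c(0L, 1L))
  if (any(bad))
    stop(sprintf("`%s` must be 0, 1 or NA; offending values: %s",
                 what, paste(unique(x[bad]), collapse = ", ")))
  x
}

#' Recover the band-call pair of a methylation state
#'
#' Inverse of [msap_state()].
#'
#' @param state character vector over [MSAP_STATES].
#' @return data.frame with integer columns `h` and `m`.
#' @export
state_bands <- function(state) {
  state <- .check_state(state)
  i <- match(state, MSAP_STATES)
  data.frame(h = c(1L, 1L, 0L, 0L)[i], m = c(1L, 0L, 1L, 0L)[i])
}

.check_state <- function(state, allow_na = TRUE) {
  state <- as.character(state)
  bad <- !is.na(state) & !(state %in% MSAP_STATES)
  if (any(bad))
    stop(sprintf("invalid methylation state(s): %s",
                 paste(unique(state[bad]), collapse = ", ")))
  if (!allow_na && anyNA(state)) stop("NA state not allowed here")
  state
}

#' Classify a reference-to-sample state transition
#'
#' Compares the methylation state of a locus in a reference plant with its
#' state in a sample and classifies the change.  States are partially ordered
#' by methylation load, `IV > {II, III} > I`: moving toward `I` is
#' `DEMETHYLATION`, away from it `METHYLATION`.  The two incomparable
#' transitions `II <-> III` (CHG vs CG context swap) form the separate
#' `INTERCHANGE` class.  Exhaustive enumeration of the 16 ordered state pairs
#' gives 4 no-change, 5 demethylation, 5 methylation and 2 interchange pairs.
#'
#' Vectorised; `NA` in either argument yields `NA`.
#'
#' @param ref,sample character vectors over [MSAP_STATES].
#' @return character vector over [TRANSITION_CLASSES].
#' @examples
#' classify_transition("III", "I")   # DEMETHYLATION (CG methylation lost)
#' classify_transition("II", "III")  # INTERCHANGE
#' @export
classify_transition <- function(ref, sample) {
  ref <- .check_state(ref)
  sample <- .check_state(sample)
  if (length(ref) == 1L) ref <- rep(ref, length(sample))
  if (length(sample) == 1L) sample <- rep(sample, length(ref))
  if (length(ref) != length(sample))
    stop("`ref` and `sample` lengths differ")
  lr <- .state_level[ref]
  ls <- .state_level[sample]
  out <- ifelse(ref == sample, "NO_CHANGE",
         ifelse(lr == ls, "INTERCHANGE",
         ifelse(ls < lr, "DEMETHYLATION", "METHYLATION")))
  out[is.na(ref) | is.na(sample)] <- NA_character_
  out
}

#' Enumerate the full transition taxonomy
#'
#' All 16 ordered (reference, sample) state pairs with their transition class
#' and a display letter: the 4 no-change pairs are labelled A-D, the 5
#' demethylation pairs E-I, the 5 methylation pairs J-N, and the 2
#' interchange pairs X1, X2.  Letters are cosmetic report labels; the ordered
#' state pair is the identity of a subclass.
#'
#' @return data.frame with columns `ref`, `sample`, `class`, `label`.
#' @export
transition_taxonomy <- function() {
  grid <- expand.grid(sample = MSAP_STATES, ref = MSAP_STATES,
                      stringsAsFactors = FALSE)[, c("ref", "sample")]
  grid$class <- classify_transition(grid$ref, grid$sample)
  grid <- grid[order(match(grid$class, TRANSITION_CLASSES),
                     match(grid$ref, MSAP_STATES),
                     match(grid$sample, MSAP_STATES)), ]
  labels <- c(LETTERS[1:4], LETTERS[5:9], LETTERS[10:14], c("X1", "X2"))
  grid$label <- labels
  rownames(grid) <- NULL
  grid
}
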