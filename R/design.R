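#' Physiological-state sample designs
#'
#' Builds the sample sheet for either assay.  The steady-state RNA design
#' samples five states (SA, IBA, Ent, Ar, SpD) with five animals each; the
#' nascent (run-on) design samples SA, IBA, Ent, ET and LT with three animals
#' each.  Each sample carries sex, a representative body temperature (Tb) and
#' the number of days spent with Tb below 8 degrees C before sampling, which
#' drives the torpor elongation-rate arithmetic: early-torpor animals average
#' 1.0 d below threshold and late-torpor animals 8.3 d, a 7.3 d difference.
#'
#' @param assay `"rna"` or `"nascent"`.
#' @param replicates_per_state number of animals per state (default 5 for
#'   RNA, 3 for nascent).
#' @param states optional custom state vector (ordered).
#' @return data.frame with columns `sample`, `state`, `replicate`, `sex`,
#'   `tb`, `days_below8`, `size_factor`.  `state` is a factor with the design
#'   order preserved.
#' @export
state_design <- function(assay = c("rna", "nascent"),
                         replicates_per_state = NULL, states = NULL) {
  assay <- match.arg(assay)
  if (is.null(states))
    states <- if (assay == "rna") c("SA", "IBA", "Ent", "Ar", "SpD")
              else c("SA", "IBA", "Ent", "ET", "LT")
  if (is.null(replicates_per_state))
    replicates_per_state <- if (assay == "rna") 5L else 3L
  stopifnot(replicates_per_state >= 1, !anyDuplicated(states))
  # representative Tb (deg C) and mean days with Tb < 8 C per state
  tb_map <- c(SA = 37, IBA = 36, Ent = 25, Ar = 10, SpD = 36.5,
              ET = 6, LT = 5.6)
  days_map <- c(SA = 0, IBA = 0.2, Ent = 0.1, Ar = 5, SpD = 0,
                ET = 1.0, LT = 8.3)
  n <- replicates_per_state
  # symmetric multiplicative per-animal offsets, zero-sum and bounded away
  # from zero so the state mean equals the map value exactly
  off <- seq_len(n) - (n + 1) / 2
  if (max(abs(off)) > 0) off <- off / max(abs(off))
  rows <- lapply(states, function(st) {
    data.frame(sample = sprintf("%s_%d", st, seq_len(n)),
               state = st, replicate = seq_len(n),
               sex = rep_len(c("F", "M"), n),
               tb = tb_map[[st]],
               days_below8 = days_map[[st]] * (1 + 0.35 * off),
               size_factor = 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$state <- factor(out$state, levels = states)
  rownames(out) <- out$sample
  out
}

#' Reference co-expression pattern libraries
#'
#' Template vectors of relative expression per state used for
#' correlation-based cluster assignment.  The steady-state library holds the
#' 14 most common dynamic patterns over (SA, IBA, Ent, Ar, SpD); the nascent
#' library holds 6 patterns over (SA, IBA, Ent, ET, LT).  Pattern families:
#' `Winter_*` separate homeotherms from heterotherms; `Cold_high_E{H,M,L}`
#' peak in the cold (Ar or torpor) with high/mid/low levels at entrance;
#' `Cold_low_*` mirror them; the remaining patterns single out one state.
#' Template values are package defaults chosen for ordinal shape only --
#' Pearson assignment is scale- and shift-invariant.
#'
#' @return numeric matrix, patterns in rows, states in columns.
#' @export
pattern_library_rna <- function() {
  states <- c("SA", "IBA", "Ent", "Ar", "SpD")
  tpl <- rbind(
    Winter_high  = c(0, 1, 1,   1, 0),
    Winter_low   = c(1, 0, 0,   0, 1),
    Cold_high_EH = c(0, 0, 1,   1, 0),
    Cold_high_EM = c(0, 0, 0.5, 1, 0),
    Cold_high_EL = c(0, 0, 0,   1, 0),
    Cold_low_EH  = c(1, 1, 0,   0, 1),
    Cold_low_EM  = c(1, 1, 0.5, 0, 1),
    Cold_low_EL  = c(1, 1, 1,   0, 1),
    IBA_high     = c(0, 1, 0,   0, 0),
    IBA_low      = c(1, 0, 1,   1, 1),
    SA_high      = c(1, 0, 0,   0, 0),
    SA_low       = c(0, 1, 1,   1, 1),
    SpD_high     = c(0, 0, 0,   0, 1),
    SpD_low      = c(1, 1, 1,   1, 0))
  colnames(tpl) <- states
  tpl
}

#' @rdname pattern_library_rna
#' @export
pattern_library_nascent <- function() {
  states <- c("SA", "IBA", "Ent", "ET", "LT")
  tpl <- rbind(
    Cold_high_EH = c(0, 0, 1,   1, 1),
    Cold_high_EM = c(0, 0, 0.5, 1, 1),
    Cold_low_EH  = c(1, 1, 0,   0, 0),
    Cold_low_EM  = c(1, 1, 0.5, 0, 0),
    IBA_high     = c(0, 1, 0,   0, 0),
    IBA_low      = c(1, 0, 1,   1, 1))
  colnames(tpl) <- states
  tpl
}

# Relative expression level implied by a pattern in a state, mapped from the
# [0, 1] template scale onto [1/dynamic_range, 1].  States absent from the
# template (ET/LT for an RNA-state library) borrow the Ar column, following
# the LT <-> Ar equivalence used when comparing the two assays.
pattern_level <- function(pattern, state, library, dynamic_range = 8) {
  lo <- 1 / dynamic_range
  if (identical(pattern, "flat")) return(rep(1, length(state)))
  if (!pattern %in% rownames(library)) stop("unknown pattern: ", pattern)
  st <- as.character(state)
  st[!st %in% colnames(library) & st %in% c("ET", "LT")] <- "Ar"
  if (any(!st %in% colnames(library)))
    stop("state(s) not covered by pattern library: ",
         paste(unique(st[!st %in% colnames(library)]), collapse = ", "))
  lo + (1 - lo) * library[pattern, st]
}
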