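#' Classify three excited states by oscillator strength and Dyson norm
#'
#' The character classifier: among the three states, the one with the
#' largest oscillator strength is the bright pi-pi* state; of the
#' remaining two, the one with the smaller Dyson norm is the Feshbach
#' resonance (bound with respect to its parent neutral, hence weakly
#' ionizing) and the other is the shape resonance.  Exactly one label is
#' assigned to each state.  Exact ties are broken deterministically (the
#' lowest state index takes the "largest"/"smallest" role) with a
#' warning.
#'
#' @param osc Numeric vector of 3 oscillator strengths (finite, >= 0).
#' @param dyson Numeric vector of 3 Dyson norms (finite, >= 0).
#' @return Character vector of length 3 with values `"bright"`,
#'   `"feshbach"`, `"shape"` — a bijection onto the three states.
#' @export
#' @examples
#' classify_states(c(1.540, 0.0874, 0.195), c(0.721, 0.345, 0.607))
classify_states <- function(osc, dyson) {
  if (length(osc) != 3L || length(dyson) != 3L ||
      any(!is.finite(osc)) || any(!is.finite(dyson)) ||
      any(osc < 0) || any(dyson < 0))
    stop("classify_states: need 3 finite nonnegative values each",
         call. = FALSE)
  labels <- character(3)
  if (sum(osc == max(osc)) > 1L)
    warning("classify_states: tie in oscillator strengths; ",
            "lowest state index takes the bright role")
  i_bright <- which.max(osc)            # lowest index wins ties
  labels[i_bright] <- "bright"
  rest <- setdiff(1:3, i_bright)
  if (dyson[rest[1]] == dyson[rest[2]])
    warning("classify_states: tie in Dyson norms; ",
            "lowest state index takes the Feshbach role")
  i_fesh <- rest[which.min(dyson[rest])]
  labels[i_fesh] <- "feshbach"
  labels[setdiff(rest, i_fesh)] <- "shape"
  labels
}

#' Relabel a record by state character at every frame
#'
#' Applies [classify_states()] independently at every frame and TBF,
#' producing character-based population dynamics: the population of a
#' character is the summed Mulliken norm of the TBFs whose occupied
#' state carries that character.  Character populations and adiabatic
#' populations therefore sum to the same total at every frame.  Because
#' classification uses the population-mixed adiabatic properties, a TBF
#' crossing the intersection diabatically keeps its character label
#' while its adiabatic state index changes.
#'
#' @param record An `ensemble_record` whose frames carry per-state
#'   oscillator strengths and Dyson norms.
#' @return A list of character frames, each a list with `time_fs`,
#'   `tbf_character` (per-TBF label of the occupied state, plus the full
#'   3-state label matrix as attribute `all_labels`) and `populations`
#'   (named numeric: bright, feshbach, shape).
#' @seealso [character_populations()] for the tidy long-format table.
#' @export
relabel_characters <- function(record) {
  validate_ensemble(record)
  fw <- record$header$family_weights
  lapply(record$frames, function(fr) {
    tb <- fr$tbfs
    need <- c("osc_1", "osc_2", "osc_3", "dyson_1", "dyson_2", "dyson_3")
    bad <- vapply(need, function(f) any(!is.finite(tb[[f]])), TRUE)
    if (any(bad))
      stop("relabel_characters: frame at t = ", fr$time_fs,
           " fs: missing/non-finite properties in ",
           paste(need[bad], collapse = ", "), call. = FALSE)
    labs <- t(vapply(seq_len(nrow(tb)), function(i)
      classify_states(c(tb$osc_1[i], tb$osc_2[i], tb$osc_3[i]),
                      c(tb$dyson_1[i], tb$dyson_2[i], tb$dyson_3[i])),
      character(3)))
    occ <- labs[cbind(seq_len(nrow(tb)), tb$state_index)]
    nw <- .frame_mulliken(tb, fw, record$header$mass_me)
    tot <- sum(nw)
    pops <- vapply(c("bright", "feshbach", "shape"),
                   function(ch) sum(nw[occ == ch]), 0)
    if (tot > 0) pops <- pops / tot
    out <- list(time_fs = fr$time_fs,
                tbf_character = occ,
                populations = pops)
    attr(out$tbf_character, "all_labels") <- labs
    out
  })
}

#' Character-based population dynamics as a tidy table
#'
#' @param record An `ensemble_record`.
#' @return Long-format data frame with columns `time_fs`, `series`
#'   (`"bright"`, `"feshbach"`, `"shape"`) and `value`, normalized so the
#'   three series sum to 1 at every frame.
#' @export
character_populations <- function(record) {
  cf <- relabel_characters(record)
  do.call(rbind, lapply(cf, function(f)
    data.frame(time_fs = f$time_fs,
               series = names(f$populations),
               value = unname(f$populations),
               stringsAsFactors = FALSE)))
}
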