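## Column schema of the per-frame TBF table.
.tbf_required <- c(
  "id", "parent_id", "family", "surface", "state_index",
  "x", "y", "px", "py", "width", "phase", "c_re", "c_im",
  "e_1", "e_2", "e_3", "theta",
  "osc_1", "osc_2", "osc_3", "dyson_1", "dyson_2", "dyson_3",
  "e_d0", "norm_w"
)

#' Construct an ensemble record
#'
#' The trajectory container used by every stage of the pipeline: a
#' self-describing header (format version, model config block, seeds,
#' time-step policy, basis conventions, per-family weights) plus a list
#' of frames ordered by time.  Each frame holds all live TBFs with
#' centroid phase-space data, complex amplitude, the three adiabatic
#' energies (ascending, eV), mixing angle, per-state oscillator
#' strengths and Dyson norms, the neutral D0 energy, and the TBF's
#' Mulliken norm times its family weight (`norm_w`).
#'
#' Times are stored in fs, positions in angstrom, energies in eV;
#' momenta, widths and phases are in atomic units (mass-weighted, with
#' the effective mass recorded in the header).
#'
#' @param model A `diabatic_model` describing the surfaces.
#' @param frames List of frames, each a list with fields `time_fs`
#'   (scalar) and `tbfs` (data frame with the schema above).
#' @param seed Integer seed recorded in the header.
#' @param family_weights Numeric vector of per-family weights (sum 1).
#' @param dt_policy Named list recording the propagation time-step
#'   policy (see [propagate()]).
#' @param width_au Frozen-Gaussian width alpha (bohr^-2).
#' @return An object of class `ensemble_record`.
#' @export
#' @examples
#' rec <- ensemble_record(build_model(), list(), seed = 1,
#'                        family_weights = numeric(0))
#' n_frames(rec)
ensemble_record <- function(model, frames = list(), seed = NA_integer_,
                            family_weights = numeric(0),
                            dt_policy = list(), width_au = NA_real_) {
  stopifnot(inherits(model, "diabatic_model"))
  rec <- list(
    header = list(
      format_version = "1.0",
      model = model_to_text(model),
      seed = seed,
      dt_policy = dt_policy,
      mass_me = .hbi_mass_au(),
      width_au = width_au,
      family_weights = family_weights,
      units = list(time = "fs", position = "angstrom", energy = "eV",
                   momentum = "au (mass-weighted)")
    ),
    frames = frames
  )
  class(rec) <- "ensemble_record"
  rec
}

#' @rdname ensemble_record
#' @param record An `ensemble_record`.
#' @export
n_frames <- function(record) length(record$frames)

#' @export
print.ensemble_record <- function(x, ...) {
  nf <- n_frames(x)
  cat(sprintf("Ensemble record: %d frame(s), %d family(ies)\n",
              nf, length(x$header$family_weights)))
  if (nf > 0) {
    t0 <- x$frames[[1]]$time_fs
    t1 <- x$frames[[nf]]$time_fs
    cat(sprintf("  time %.3f .. %.3f fs; %d TBF(s) in final frame\n",
                t0, t1, nrow(x$frames[[nf]]$tbfs)))
  }
  cat(sprintf("  seed %s, width %.4g bohr^-2\n",
              format(x$header$seed), x$header$width_au))
  invisible(x)
}

#' Retrieve the model stored in a record header
#' @param record An `ensemble_record`.
#' @return The `diabatic_model` parsed from the header config block.
#' @export
record_model <- function(record) model_from_text(record$header$model)

#' Validate an ensemble record against the trajectory schema
#'
#' Checks the header, frame ordering, the TBF column schema and the type
#' invariants (amplitude bound, ascending adiabatic energies, nonnegative
#' properties and weights, positive widths).  Errors name the offending
#' frame and field.
#'
#' @param record An `ensemble_record`.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_ensemble <- function(record) {
  if (!inherits(record, "ensemble_record"))
    stop("validate_ensemble: not an ensemble_record", call. = FALSE)
  h <- record$header
  if (!identical(h$format_version, "1.0"))
    stop("validate_ensemble: unsupported format_version", call. = FALSE)
  if (length(h$family_weights) &&
      (any(h$family_weights < 0) ||
       abs(sum(h$family_weights) - 1) > 1e-6))
    stop("validate_ensemble: header family_weights must be nonnegative ",
         "and sum to 1", call. = FALSE)
  times <- vapply(record$frames, function(f) f$time_fs, 0)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("validate_ensemble: frame times must be strictly increasing ",
         "(frame ", which(diff(times) <= 0)[1] + 1, ")", call. = FALSE)
  for (i in seq_along(record$frames)) {
    tb <- record$frames[[i]]$tbfs
    if (!is.data.frame(tb))
      stop("validate_ensemble: frame ", i, ": tbfs is not a data frame",
           call. = FALSE)
    missing_cols <- setdiff(.tbf_required, names(tb))
    if (length(missing_cols))
      stop("validate_ensemble: frame ", i, ": missing field(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    ## amplitude bound: the squared norm in the overlap metric cannot
    ## exceed 1 (per family; for a single-TBF family this is |c|^2)
    for (fam in unique(tb$family)) {
      sel <- tb[tb$family == fam, , drop = FALSE]
      xb <- cbind(angstrom_to_bohr(sel$x), angstrom_to_bohr(sel$y))
      s <- .gauss_overlap(xb, cbind(sel$px, sel$py), sel$phase,
                          sel$width[1], state = sel$surface)
      cc <- complex(real = sel$c_re, imaginary = sel$c_im)
      if (Re(Conj(cc) %*% s %*% cc)[1] > 1 + 1e-6)
        stop("validate_ensemble: frame ", i,
             ": field c_re/c_im: family ", fam,
             " amplitude norm |c|^2 > 1", call. = FALSE)
    }
    if (any(tb$e_2 < tb$e_1) || any(tb$e_3 < tb$e_2))
      stop("validate_ensemble: frame ", i,
           ": field e_1..e_3: adiabatic energies not ascending",
           call. = FALSE)
    for (f in c("osc_1", "osc_2", "osc_3", "dyson_1", "dyson_2", "dyson_3"))
      if (any(!is.finite(tb[[f]])) || any(tb[[f]] < 0))
        stop("validate_ensemble: frame ", i, ": field ", f,
             ": missing or negative value", call. = FALSE)
    if (any(tb$width <= 0))
      stop("validate_ensemble: frame ", i, ": field width: must be > 0",
           call. = FALSE)
    if (any(tb$norm_w < -1e-6))
      stop("validate_ensemble: frame ", i,
           ": field norm_w: negative weight", call. = FALSE)
    if (any(!tb$state_index %in% 1:3))
      stop("validate_ensemble: frame ", i,
           ": field state_index: must be 1, 2 or 3", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write ensemble records
#'
#' Records are stored as a single self-describing JSON document (text,
#' versioned header).  Writing then reading is lossless at full double
#' precision; [read_ensemble()] validates the record before returning
#' it.
#'
#' @param record An `ensemble_record`.
#' @param path File path.
#' @return `read_ensemble()` returns a validated `ensemble_record`;
#'   `write_ensemble()` returns `path` invisibly.
#' @export
#' @examples
#' p <- tempfile(fileext = ".json")
#' write_ensemble(ensemble_record(build_model(), list(), 1, numeric(0)), p)
#' rec <- read_ensemble(p)
write_ensemble <- function(record, path) {
  validate_ensemble(record)
  json <- jsonlite::toJSON(unclass(record), digits = I(17), auto_unbox = TRUE,
                           null = "null", na = "null", pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path))
    stop("read_ensemble: no such file: ", path, call. = FALSE)
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                       simplifyMatrix = FALSE),
    error = function(e) stop("read_ensemble: parse error: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(obj$header) || is.null(obj$header$format_version))
    stop("read_ensemble: parse error: missing header/format_version",
         call. = FALSE)
  frames <- obj$frames
  if (is.null(frames)) frames <- list()
  if (is.data.frame(frames))   # jsonlite may tabulate homogeneous frames
    frames <- lapply(seq_len(nrow(frames)), function(i)
      list(time_fs = frames$time_fs[i], tbfs = frames$tbfs[[i]]))
  int_cols <- c("id", "parent_id", "family", "state_index")
  frames <- lapply(frames, function(f) {
    tb <- as.data.frame(f$tbfs)
    if (nrow(tb)) {
      ## canonical column types (JSON has no int/double distinction)
      for (cc in intersect(int_cols, names(tb)))
        tb[[cc]] <- as.integer(tb[[cc]])
      for (cc in setdiff(intersect(.tbf_required, names(tb)),
                         c(int_cols, "surface")))
        tb[[cc]] <- as.double(tb[[cc]])
      tb$surface <- as.character(tb$surface)
      attr(tb, "row.names") <- seq_len(nrow(tb))
    }
    list(time_fs = f$time_fs, tbfs = tb)
  })
  rec <- list(header = obj$header, frames = frames)
  rec$header$family_weights <- as.numeric(rec$header$family_weights)
  class(rec) <- "ensemble_record"
  validate_ensemble(rec)
  rec
}

## Build one row of the TBF table from an evaluated electronic point.
## `surface` is "lower" or "upper"; positions in angstrom, momenta/width/
## phase in atomic units; camp is the complex amplitude.
.tbf_row <- function(model, id, parent_id, family, surface,
                     x, y, px, py, width, phase, camp, norm_w) {
  pt <- evaluate_model(model, x, y)
  data.frame(
    id = id, parent_id = parent_id, family = family, surface = surface,
    state_index = match(surface, pt$surface),
    x = x, y = y, px = px, py = py, width = width, phase = phase,
    c_re = Re(camp), c_im = Im(camp),
    e_1 = pt$energies[1], e_2 = pt$energies[2], e_3 = pt$energies[3],
    theta = pt$theta,
    osc_1 = pt$osc[1], osc_2 = pt$osc[2], osc_3 = pt$osc[3],
    dyson_1 = pt$dyson[1], dyson_2 = pt$dyson[2], dyson_3 = pt$dyson[3],
    e_d0 = pt$e_d0, norm_w = norm_w,
    stringsAsFactors = FALSE
  )
}

## Mulliken-partitioned norms of the TBFs in one frame, recomputed from
## stored amplitudes and centroids: n_j = Re[c_j^* (S c)_j] within each
## family (basis functions on different adiabats are orthogonal), scaled
## by the family weight.  Returns a numeric vector aligned with the rows
## of `tbfs`.
.frame_mulliken <- function(tbfs, family_weights, mass_me) {
  out <- numeric(nrow(tbfs))
  for (fam in unique(tbfs$family)) {
    idx <- which(tbfs$family == fam)
    tb <- tbfs[idx, , drop = FALSE]
    xb <- cbind(angstrom_to_bohr(tb$x), angstrom_to_bohr(tb$y))
    pb <- cbind(tb$px, tb$py)
    s <- .gauss_overlap(xb, pb, tb$phase, tb$width[1], state = tb$surface)
    cc <- complex(real = tb$c_re, imaginary = tb$c_im)
    n <- Re(Conj(cc) * as.vector(s %*% cc))
    ## Mulliken partitioning can assign small negative shares to
    ## strongly overlapping TBFs; truncate and renormalize so the
    ## per-family partition stays a probability.
    n <- pmax(n, 0)
    tot <- sum(n)
    if (tot > 0) n <- n / tot
    w <- if (length(family_weights) >= fam) family_weights[fam] else 1
    out[idx] <- n * w
  }
  out
}
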