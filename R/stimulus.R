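#' Onset time of an SQM frame
#'
#' Frame 0 is the central line, presented at t = 0 for 20 ms; flanking
#' pair n follows after a first inter-stimulus interval of 30 ms and
#' subsequent ISIs of 20 ms, so pair n starts at `50 + 40*(n - 1)` ms.
#'
#' @param frame Non-negative integer frame index (vectorised).
#' @return Onset time(s) in ms.
#' @examples
#' frame_onset(c(0, 1, 7, 11, 14)) # 0, 50, 290, 450, 570
#' @export
frame_onset <- function(frame) {
  if (length(frame) == 0L) return(numeric(0))
  if (any(!is.finite(frame)) || any(frame < 0) || any(frame != floor(frame)))
    stop("'frame' must be non-negative integer indices (0 = central line)")
  ifelse(frame == 0, 0, 50 + 40 * (frame - 1))
}

# duration of every line element (ms)
.LINE_MS <- 20
# gap between the central line and the first flanks, and between
# consecutive flanks (arcmin); forced by the printed separations
# 13.3' over 4 gaps and 26.7' over 8 gaps
.FLANK_SPACING <- 3.33

#' Specify an SQM condition
#'
#' A condition names which frames carry a vernier offset and with which
#' sign (+1 pro-vernier, -1 anti-vernier), how many flanking pairs the
#' stream has, the motion variant, the report instruction, and which
#' offset serves as the reference for "dominance in accordance".
#'
#' @param name Condition label, e.g. `"V-AV8"`.
#' @param offsets Named numeric vector mapping frame index to offset sign;
#'   names are frame indices as strings (`"0"` is the central line),
#'   values must be in `{-1, 0, 1}`.
#' @param n_pairs Number of flanking pairs.
#' @param variant `"diverging"` (classic SQM) or
#'   `"diverging_then_converging"` (streams switch direction at frame 10).
#' @param instruction `"naive"`, `"R1"` (report first vernier) or
#'   `"R2"` (report second vernier).
#' @param reference Which offset defines dominance-in-accordance:
#'   `"central_vernier"`, `"first_vernier"` or `"second_vernier"`.
#' @return An object of class `"sqm_condition"`.
#' @examples
#' condition_spec("V-AV8", c("0" = 1, "8" = -1), instruction = "R2")
#' @export
condition_spec <- function(name, offsets, n_pairs = 18,
                           variant = c("diverging", "diverging_then_converging"),
                           instruction = c("naive", "R1", "R2"),
                           reference = c("central_vernier", "first_vernier",
                                         "second_vernier")) {
  variant <- match.arg(variant)
  instruction <- match.arg(instruction)
  reference <- match.arg(reference)
  if (is.list(offsets)) offsets <- unlist(offsets)
  if (length(offsets) == 0L)
    offsets <- stats::setNames(numeric(0), character(0))
  if (is.null(names(offsets)) || any(names(offsets) == ""))
    stop("'offsets' must be a named vector: names are frame indices")
  frames <- suppressWarnings(as.integer(names(offsets)))
  if (any(is.na(frames)) || any(frames < 0))
    stop("offset frame indices must be non-negative integers")
  if (any(frames > n_pairs))
    stop("offset frame index beyond 'n_pairs' (", n_pairs, ")")
  if (!all(offsets %in% c(-1, 0, 1)))
    stop("offset signs must be -1, 0 or +1")
  structure(
    list(name = name,
         offsets = stats::setNames(as.numeric(offsets), as.character(frames)),
         n_pairs = as.integer(n_pairs), variant = variant,
         instruction = instruction, reference = reference),
    class = "sqm_condition"
  )
}

#' @export
print.sqm_condition <- function(x, ...) {
  off <- if (length(x$offsets))
    paste(sprintf("%s:%+d", names(x$offsets), as.integer(x$offsets)),
          collapse = ", ")
  else "none"
  cat(sprintf("SQM condition %s [%s]\n", x$name, x$instruction))
  cat(sprintf("  offsets {%s}, %d flanking pairs, %s, reference = %s\n",
              off, x$n_pairs, x$variant, x$reference))
  invisible(x)
}

#' Build an SQM stimulus sequence
#'
#' Expands a condition into timed, positioned line elements: one central
#' line plus `2 * n_pairs` flanking lines forming a left and a right
#' apparent-motion stream. Offsets are applied only to the attended
#' stream's element (and the central line) at the frames named in the
#' condition; the unattended stream is always aligned.
#'
#' @param spec An [condition_spec()] object.
#' @param attended_stream `"right"` or `"left"`.
#' @param geometry `"increasing"` (flank length 11.7' growing by 1.7' per
#'   frame, the experiment 1-2 layout) or `"constant"` (all flanks 20').
#' @return An object of class `"sqm_sequence"`: a list with an `elements`
#'   data frame (`location_id`, `frame`, `onset_ms`, `duration_ms`,
#'   `eccentricity_arcmin`, `length_arcmin`, `offset_sign`) plus the
#'   condition metadata and the total stimulus `duration_ms`.
#' @examples
#' seq <- build_sequence(condition_spec("V", c("0" = 1)))
#' seq$duration_ms # 750
#' @export
build_sequence <- function(spec, attended_stream = c("right", "left"),
                           geometry = c("increasing", "constant")) {
  stopifnot(inherits(spec, "sqm_condition"))
  attended_stream <- match.arg(attended_stream)
  geometry <- match.arg(geometry)
  n <- spec$n_pairs
  frames <- seq_len(n)
  onsets <- frame_onset(frames)
  ecc <- if (spec$variant == "diverging_then_converging")
    .FLANK_SPACING * ifelse(frames <= 10, frames, 2 * 10 - frames)
  else .FLANK_SPACING * frames
  len <- if (geometry == "increasing") 11.7 + 1.7 * (frames - 1) else rep(20, n)

  att_sign <- if (attended_stream == "right") 1L else -1L
  elements <- data.frame(
    location_id = c(0L, att_sign * frames, -att_sign * frames),
    frame = c(0L, frames, frames),
    onset_ms = c(0, onsets, onsets),
    duration_ms = .LINE_MS,
    eccentricity_arcmin = c(0, ecc, ecc),
    length_arcmin = c(20, len, len),
    offset_sign = 0
  )
  for (f in names(spec$offsets)) {
    fi <- as.integer(f)
    target <- if (fi == 0L) elements$location_id == 0L else
      elements$frame == fi & sign(elements$location_id) == att_sign
    elements$offset_sign[target] <- spec$offsets[[f]]
  }
  elements <- elements[order(elements$onset_ms, elements$location_id), ]
  rownames(elements) <- NULL
  structure(
    list(elements = elements, n_pairs = n, variant = spec$variant,
         attended_stream = attended_stream, condition = spec,
         duration_ms = frame_onset(n) + .LINE_MS),
    class = "sqm_sequence"
  )
}

#' @export
print.sqm_sequence <- function(x, ...) {
  cat(sprintf("SQM sequence '%s': %d elements, %d pairs, %g ms, attending %s\n",
              x$condition$name, nrow(x$elements), x$n_pairs, x$duration_ms,
              x$attended_stream))
  invisible(x)
}

#' Piecewise-constant feature signal of one element
#'
#' The model's `stim(t)` for a single retinal location: equal to the
#' element's offset sign during its presentation and 0 elsewhere.
#'
#' @param seq An [build_sequence()] result.
#' @param location_id Integer location (0 = centre, +n / -n = n-th flank
#'   of the right / left stream).
#' @return A data frame with columns `t_on`, `t_off` (ms) and `value`,
#'   one row per presentation interval; the signal is 0 outside the
#'   listed intervals.
#' @export
element_signal <- function(seq, location_id) {
  stopifnot(inherits(seq, "sqm_sequence"))
  el <- seq$elements[seq$elements$location_id == location_id, ]
  if (nrow(el) == 0L)
    stop("no element at location ", location_id, " in this sequence")
  data.frame(t_on = el$onset_ms, t_off = el$onset_ms + el$duration_ms,
             value = el$offset_sign)
}

#' Library of published SQM conditions
#'
#' All conditions used across the four experiments: the single-offset
#' calibration conditions (V, AV and per-frame variants), the two-offset
#' probes V-AVn / V-PVn for frames 1, 2, 3, 5, 7, 11 and 14, the
#' window-boundary conditions around frames 8 and 12 (V-AV8, V-AV12,
#' V-AV8-PV12, PV8-PV12, PV8-AV12, PV1-AV5), and the 20-pair
#' diverging-then-converging conditions C1-C5. Report-instruction
#' variants are separate entries named e.g. `"V-AV8 [R2]"`.
#'
#' @return A named list of [condition_spec()] objects.
#' @examples
#' names(condition_library())[1:5]
#' condition_library()[["V-AV8-PV12 [R2]"]]
#' @export
condition_library <- function() {
  lib <- list()
  add <- function(spec) lib[[spec$name]] <<- spec
  lab <- function(base, instr)
    if (instr == "naive") base else sprintf("%s [%s]", base, instr)

  # experiment 1: 18 pairs, central vernier plus one flank vernier
  add(condition_spec("V", c("0" = 1)))
  add(condition_spec("AV", c("7" = -1)))
  for (n in c(1, 2, 3, 5, 7, 11, 14)) {
    fo <- as.character(n)
    add(condition_spec(sprintf("AV%d", n),
                       stats::setNames(-1, fo)))
    for (instr in c("naive", "R1")) {
      add(condition_spec(lab(sprintf("V-AV%d", n), instr),
                         stats::setNames(c(1, -1), c("0", fo)),
                         instruction = instr))
      add(condition_spec(lab(sprintf("V-PV%d", n), instr),
                         stats::setNames(c(1, 1), c("0", fo)),
                         instruction = instr))
    }
  }

  # experiment 2: offsets straddling the 425-ms window boundary
  add(condition_spec("V-AV8 [R2]", c("0" = 1, "8" = -1), instruction = "R2"))
  add(condition_spec("V-AV12 [R2]", c("0" = 1, "12" = -1), instruction = "R2"))
  for (instr in c("R1", "R2"))
    add(condition_spec(lab("V-AV8-PV12", instr),
                       c("0" = 1, "8" = -1, "12" = 1), instruction = instr))

  # experiment 3: no central offset; constant-length flanks
  for (instr in c("R1", "R2")) {
    add(condition_spec(lab("PV8-PV12", instr), c("8" = 1, "12" = 1),
                       instruction = instr,
                       reference = if (instr == "R1") "first_vernier"
                       else "second_vernier"))
    add(condition_spec(lab("PV8-AV12", instr), c("8" = 1, "12" = -1),
                       instruction = instr,
                       reference = if (instr == "R1") "first_vernier"
                       else "second_vernier"))
    add(condition_spec(lab("PV1-AV5", instr), c("1" = 1, "5" = -1),
                       instruction = instr,
                       reference = if (instr == "R1") "first_vernier"
                       else "second_vernier"))
  }

  # experiment 4: 20 pairs, diverging then converging at frame 10;
  # three possible offsets per window (frames 1, 5, 8 and 12, 15, 19)
  c4 <- list(C1 = c("1" = 1, "5" = -1, "8" = 1),
             C2 = c("12" = -1, "15" = 1, "19" = -1),
             C3 = c("1" = 1, "5" = -1, "8" = 1, "15" = 1),
             C4 = c("5" = -1, "12" = -1, "15" = 1, "19" = -1),
             C5 = c("1" = 1, "5" = -1, "8" = 1,
                    "12" = -1, "15" = 1, "19" = -1))
  for (nm in names(c4)) for (instr in c("R1", "R2"))
    add(condition_spec(lab(nm, instr), c4[[nm]], n_pairs = 20,
                       variant = "diverging_then_converging",
                       instruction = instr,
                       reference = if (instr == "R1") "first_vernier"
                       else "second_vernier"))
  lib
}

#' Look up a condition by name
#'
#' @param name Entry name in [condition_library()], e.g. `"V-AV12 [R2]"`.
#' @return The matching [condition_spec()] object.
#' @export
get_condition <- function(name) {
  lib <- condition_library()
  if (!name %in% names(lib))
    stop("unknown condition '", name, "'; see names(condition_library())")
  lib[[name]]
}

# sign of the offset that defines "dominance in accordance"
reference_sign <- function(spec) {
  off <- spec$offsets[spec$offsets != 0]
  if (length(off) == 0L) return(1)
  frames <- as.integer(names(off))
  s <- switch(spec$reference,
    central_vernier = if ("0" %in% names(off)) off[["0"]] else 1,
    first_vernier = off[[which.min(frames)]],
    second_vernier = off[[which.max(frames)]]
  )
  if (s == 0) 1 else s
}

#' Export a stimulus sequence as a flat table
#'
#' @param seq An [build_sequence()] result.
#' @param file Optional path; when given the table is written as CSV.
#' @return The `elements` data frame, invisibly when `file` is given.
#' @export
sequence_table <- function(seq, file = NULL) {
  stopifnot(inherits(seq, "sqm_sequence"))
  tab <- seq$elements
  if (!is.null(file)) {
    utils::write.csv(tab, file, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
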