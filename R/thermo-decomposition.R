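#' Thermodynamic cycle specification
#'
#' A closed loop of relative binding free-energy legs over ligand states,
#' e.g. `2->4`, `4->3`, `3->2`. Each leg carries its estimate, SEM and an
#' orientation: orientation -1 traverses the labelled transformation in
#' reverse (so a measured `2->3` leg can close a `... -> 3 -> 2 -> ...`
#' loop).
#'
#' @param labels character state-pair labels of the form "A->B".
#' @param ddG measured leg values (kcal/mol).
#' @param sem per-leg SEMs (kcal/mol; default 0).
#' @param orientation +1 / -1 traversal direction per leg (default +1).
#' @return list of class `cycle_spec`; errors name unmatched states if the
#'   oriented legs do not form a single closed loop.
#' @export
cycle_spec <- function(labels, ddG, sem = NULL, orientation = NULL) {
  n <- length(labels)
  stopifnot(length(ddG) == n, n >= 2)
  if (is.null(sem)) sem <- rep(0, n)
  if (is.null(orientation)) orientation <- rep(1, n)
  stopifnot(length(sem) == n, length(orientation) == n,
            all(orientation %in% c(-1, 1)))
  parts <- strsplit(labels, "->", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("leg labels must have the form 'A->B'")
  from <- trimws(vapply(parts, `[`, "", 1))
  to <- trimws(vapply(parts, `[`, "", 2))
  src <- ifelse(orientation == 1, from, to)
  dst <- ifelse(orientation == 1, to, from)
  bad_out <- src[duplicated(src)]
  bad_in <- dst[duplicated(dst)]
  unmatched <- union(setdiff(src, dst), setdiff(dst, src))
  if (length(bad_out) || length(bad_in) || length(unmatched))
    stop("legs do not form a closed loop; unmatched state(s): ",
         paste(unique(c(unmatched, bad_out, bad_in)), collapse = ", "))
  structure(list(labels = labels, from = from, to = to, ddG = ddG,
                 sem = sem, orientation = orientation),
            class = "cycle_spec")
}

#' Thermodynamic-cycle closure
#'
#' Signed sum of the legs around the loop; a perfectly consistent set of
#' calculations closes at 0, and the closure magnitude relative to its
#' propagated SEM (\eqn{\sqrt{\sum sem_i^2}}) measures convergence.
#'
#' @param spec a [cycle_spec()].
#' @return list of class `cycle_closure`: `closure` (kcal/mol), `sem`,
#'   `n_legs`.
#' @export
cycle_closure <- function(spec) {
  stopifnot(inherits(spec, "cycle_spec"))
  structure(list(closure = sum(spec$orientation * spec$ddG),
                 sem = sqrt(sum(spec$sem^2)),
                 n_legs = length(spec$ddG)),
            class = "cycle_closure")
}

#' @export
print.cycle_closure <- function(x, ...) {
  cat(sprintf("cycle closure = %.4g +/- %.2g kcal/mol over %d legs\n",
              x$closure, x$sem, x$n_legs))
  invisible(x)
}

#' Two-temperature enthalpy-entropy decomposition
#'
#' Finite-temperature-difference (van't Hoff) decomposition of a relative
#' binding free energy measured at two temperatures:
#' \deqn{\Delta\Delta S = -\frac{\Delta\Delta G(T_2) - \Delta\Delta G(T_1)}
#'   {T_2 - T_1}, \qquad
#'   \Delta\Delta H = \Delta\Delta G(T_2) + T_2 \Delta\Delta S,}
#' with \eqn{-T\Delta\Delta S} reported at `report_T`. SEMs are propagated
#' linearly treating the two inputs as independent:
#' \eqn{sem(\Delta\Delta S) = \sqrt{sem_1^2 + sem_2^2} / |T_2 - T_1|},
#' \eqn{sem(\Delta\Delta H) = \sqrt{sem_2^2 + T_2^2\, sem(\Delta\Delta S)^2}}.
#' The identity \eqn{\Delta\Delta H - T_2 \Delta\Delta S =
#' \Delta\Delta G(T_2)} holds exactly by construction.
#'
#' @param ddG_T1,ddG_T2 free-energy differences (kcal/mol) at `T1`, `T2`.
#' @param T1,T2 temperatures (K), distinct; defaults 288.15 and 298.15.
#' @param sem_T1,sem_T2 input SEMs (kcal/mol, default 0).
#' @param report_T temperature for the \eqn{-T\Delta\Delta S} column
#'   (default `T2`).
#' @param label transformation label carried through.
#' @return list of class `thermo_decomposition` with fields `ddS`, `ddH`,
#'   `minus_T_ddS` and their SEMs, plus the inputs.
#' @export
vant_hoff_decompose <- function(ddG_T1, ddG_T2, T1 = 288.15, T2 = 298.15,
                                sem_T1 = 0, sem_T2 = 0, report_T = T2,
                                label = "") {
  if (T1 == T2) stop("temperatures must differ")
  ddG_T1 <- unname(ddG_T1); ddG_T2 <- unname(ddG_T2)
  dT <- T2 - T1
  ddS <- -(ddG_T2 - ddG_T1) / dT
  ddH <- ddG_T2 + T2 * ddS
  minus_T_ddS <- -report_T * ddS
  sem_S <- sqrt(sem_T1^2 + sem_T2^2) / abs(dT)
  sem_H <- sqrt(sem_T2^2 + T2^2 * sem_S^2)
  structure(list(label = label, T1 = T1, T2 = T2,
                 ddG_T1 = ddG_T1, ddG_T2 = ddG_T2,
                 sem_T1 = sem_T1, sem_T2 = sem_T2,
                 ddS = ddS, sem_ddS = sem_S,
                 ddH = ddH, sem_ddH = sem_H,
                 report_T = report_T,
                 minus_T_ddS = minus_T_ddS,
                 sem_minus_T_ddS = report_T * sem_S),
            class = "thermo_decomposition")
}

#' @export
print.thermo_decomposition <- function(x, ...) {
  cat(sprintf(
    "%sddG(%g K) = %.4g +/- %.2g; ddH = %.4g +/- %.2g; -T ddS(%g K) = %.4g +/- %.2g kcal/mol\n",
    if (nzchar(x$label)) paste0(x$label, ": ") else "",
    x$T2, x$ddG_T2, x$sem_T2, x$ddH, x$sem_ddH, x$report_T,
    x$minus_T_ddS, x$sem_minus_T_ddS))
  invisible(x)
}

#' Tabulate decompositions in report layout
#'
#' One row per transformation with the unrounded machine-readable values
#' and display columns rounded the way such tables are conventionally
#' printed (free energies to 1 decimal; enthalpic/entropic components to
#' the nearest 10, reflecting their much larger propagated errors).
#'
#' @param decomps list of [vant_hoff_decompose()] results.
#' @return data.frame, one row per transformation.
#' @export
decomposition_table <- function(decomps) {
  if (inherits(decomps, "thermo_decomposition")) decomps <- list(decomps)
  do.call(rbind, lapply(decomps, function(d) data.frame(
    transformation = d$label,
    ddG_T1 = d$ddG_T1, sem_T1 = d$sem_T1,
    ddG_T2 = d$ddG_T2, sem_T2 = d$sem_T2,
    ddH = d$ddH, sem_ddH = d$sem_ddH,
    minus_T_ddS = d$minus_T_ddS, sem_minus_T_ddS = d$sem_minus_T_ddS,
    ddG_T1_print = round(d$ddG_T1, 1), ddG_T2_print = round(d$ddG_T2, 1),
    ddH_print = round(d$ddH, -1), minus_T_ddS_print = round(d$minus_T_ddS, -1),
    stringsAsFactors = FALSE)))
}
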