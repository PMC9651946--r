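#' Closed-loop feedback decomposition
#'
#' The algebra that separates the three sources of sensory feedback driving
#' the head — visual feedback from head motion, visual feedback from body
#' motion, and nested mechanosensory feedback from body motion — and that
#' estimates the hidden body-to-head mechanosensory transform from
#' measurable closed-loop transforms. All operations are element-wise on a
#' shared frequency grid; inputs measured on different grids must be
#' co-gridded upstream.
#'
#' @name decompose
NULL

align_frfs <- function(frs) {
  grid <- frs[[1]]$freq_hz
  for (fr in frs) {
    stopifnot(inherits(fr, "fly_frf"))
    if (!isTRUE(all.equal(fr$freq_hz, grid))) {
      rlang::abort("transforms are not on a shared frequency grid.")
    }
  }
  grid
}

frf_values <- function(fr) fr$response

flag_near_singular <- function(den, floor = 1e-8) Mod(den) >= floor

# --- pure complex-vector forms (shared with uncertainty propagation) --------

eq_head_free_terms <- function(Gv, Gm, BoR) {
  den <- 1 + Gv
  list(head_visual = Gv / den,
       body_visual = -(Gv / den) * BoR,
       body_mech = (Gm / den) * BoR)
}

eq_head_fixed <- function(Gv) Gv / (1 + Gv)

#' Registered decomposition expressions for uncertainty propagation
#'
#' Named functions mapping a named list of complex transform vectors to the
#' complex output of a decomposition formula. Used by
#' [propagate_uncertainty()] so that dispersion can be pushed through
#' formulas whose inputs come from different groups of animals.
#'
#' @return Named list of functions. Names: `closed_loop_free` (inputs `Gv`,
#'   `Gm`, `BoR`), `closed_loop_fixed` (`Gv`), `visual_only` (`Gv`, `BoR`),
#'   `mechano_only` (`GvM`), `gm_self` (`Gv`, `HoR`, `BoR`),
#'   `gm_external_printed` / `gm_external_rederived` (`Gv`, `HoB`),
#'   `feedback_weighting` (`GvM`, `Gv`).
#' @export
decompose_expressions <- function() {
  list(
    closed_loop_free = function(x) {
      tm <- eq_head_free_terms(x$Gv, x$Gm, x$BoR)
      tm$head_visual + tm$body_visual + tm$body_mech
    },
    closed_loop_fixed = function(x) eq_head_fixed(x$Gv),
    visual_only = function(x) {
      tm <- eq_head_free_terms(x$Gv, 0 + 0i, x$BoR)
      tm$head_visual + tm$body_visual
    },
    mechano_only = function(x) x$GvM / (1 + x$GvM),
    gm_self = function(x) {
      (1 + x$Gv) * (x$HoR / x$BoR) - x$Gv / x$BoR + x$Gv
    },
    gm_external_printed = function(x) (1 - x$Gv) * x$HoB,
    gm_external_rederived = function(x) (1 + x$Gv) * x$HoB,
    feedback_weighting = function(x) x$GvM / x$Gv
  )
}

#' Closed-loop head transform of a body-free animal, by feedback source
#'
#' `H/R = Gv/(1+Gv) - Gv/(1+Gv) * B/R + Gm/(1+Gv) * B/R`: the head-visual,
#' body-visual, and body-mechanosensory terms of the body-free closed loop.
#' The three addends are returned separately alongside their sum.
#'
#' @param Gv `fly_frf`, the visual transform E to H (body-fixed animals).
#' @param Gm `fly_frf`, the mechanosensory transform B to H.
#' @param B_over_R `fly_frf`, the closed-loop body response R to B.
#' @param floor Near-singularity floor on `|1 + Gv|`; frequencies below it
#'   are flagged `valid = FALSE`.
#' @return Tibble with `freq_hz`, complex columns `term_head_visual`,
#'   `term_body_visual`, `term_body_mech`, `total`, plus `gain`,
#'   `phase_deg`, `is_stim`, `valid`.
#' @examples
#' g <- new_frf(1, 1 + 0i, TRUE, TRUE)
#' b <- new_frf(1, 0.5 + 0i, TRUE, TRUE)
#' closed_loop_head_free(g, g, b)$total # 0.5 - 0.25 + 0.25 = 0.5
#' @export
closed_loop_head_free <- function(Gv, Gm, B_over_R, floor = 1e-8) {
  grid <- align_frfs(list(Gv, Gm, B_over_R))
  gv <- frf_values(Gv); gm <- frf_values(Gm); br <- frf_values(B_over_R)
  ok <- flag_near_singular(1 + gv, floor)
  tm <- eq_head_free_terms(gv, gm, br)
  total <- tm$head_visual + tm$body_visual + tm$body_mech
  tibble::tibble(
    freq_hz = grid,
    term_head_visual = tm$head_visual,
    term_body_visual = tm$body_visual,
    term_body_mech = tm$body_mech,
    total = total,
    gain = Mod(total),
    phase_deg = wrap_deg(Arg(total) * 180 / pi),
    is_stim = Gv$is_stim,
    valid = ok & Gv$valid & Gm$valid & B_over_R$valid
  )
}

#' Closed-loop head transform of a body-fixed animal
#'
#' `H/R = Gv / (1 + Gv)`: only visual feedback from head movements remains
#' when the body is clamped.
#'
#' @inheritParams closed_loop_head_free
#' @return A `fly_frf` tibble.
#' @export
closed_loop_head_fixed <- function(Gv, floor = 1e-8) {
  gv <- frf_values(Gv)
  ok <- flag_near_singular(1 + gv, floor)
  new_frf(Gv$freq_hz, eq_head_fixed(gv), Gv$is_stim, ok & Gv$valid,
          n_flies = attr(Gv, "n_flies"))
}

#' Predicted head transform with body visual feedback only
#'
#' The body-free closed loop with the mechanosensory term removed
#' (`Gm = 0`): `H/R = Gv/(1+Gv) * (1 - B/R)`. This is the model prediction
#' that a replay experiment (reintroducing body visual feedback to
#' body-fixed animals) tests directly.
#'
#' @inheritParams closed_loop_head_free
#' @return A `fly_frf` tibble.
#' @export
predict_visual_only <- function(Gv, B_over_R, floor = 1e-8) {
  grid <- align_frfs(list(Gv, B_over_R))
  gv <- frf_values(Gv); br <- frf_values(B_over_R)
  ok <- flag_near_singular(1 + gv, floor)
  tm <- eq_head_free_terms(gv, 0 + 0i, br)
  new_frf(grid, tm$head_visual + tm$body_visual, Gv$is_stim,
          ok & Gv$valid & B_over_R$valid, n_flies = attr(Gv, "n_flies"))
}

#' Predicted head transform with nested mechanosensory feedback folded in
#'
#' `H/R = GvM / (1 + GvM)` where `GvM` is the E-to-H transform of body-free
#' animals (which already contains the nested mechanosensory contribution).
#'
#' @param GvM `fly_frf`, the E-to-H transform measured body-free.
#' @inheritParams closed_loop_head_free
#' @return A `fly_frf` tibble.
#' @export
predict_mechano_only <- function(GvM, floor = 1e-8) {
  gvm <- frf_values(GvM)
  ok <- flag_near_singular(1 + gvm, floor)
  new_frf(GvM$freq_hz, gvm / (1 + gvm), GvM$is_stim, ok & GvM$valid,
          n_flies = attr(GvM, "n_flies"))
}

#' Estimate the mechanosensory transform from self-generated body motion
#'
#' Inverts the body-free closed loop for the hidden B-to-H transform:
#' `Gm = (1 + Gv) H/B - Gv R/B + Gv`, with `H/B = (H/R)/(B/R)` and
#' `R/B = 1/(B/R)`. The algebraically equivalent form
#' `Gm = (GvM - Gv) E/B`, with `GvM = (H/R)/(E/R)` and
#' `E/R = 1 - H/R - B/R`, is computed as a cross-check and returned
#' alongside.
#'
#' @param Gv `fly_frf`, visual transform (body-fixed).
#' @param H_over_R_free `fly_frf`, closed-loop head transform (body-free).
#' @param B_over_R `fly_frf`, closed-loop body transform (body-free).
#' @param floor Minimum `|B/R|`; below it the body barely moves and the
#'   frequency is flagged invalid.
#' @return Tibble with `freq_hz`, complex `Gm` (primary form), `Gm_alt`
#'   (cross-check form), `gain`, `phase_deg`, `is_stim`, `valid`.
#' @export
estimate_Gm_self <- function(Gv, H_over_R_free, B_over_R, floor = 1e-3) {
  grid <- align_frfs(list(Gv, H_over_R_free, B_over_R))
  gv <- frf_values(Gv)
  hr <- frf_values(H_over_R_free)
  br <- frf_values(B_over_R)
  ok <- Mod(br) >= floor
  hb <- hr / br
  gm <- (1 + gv) * hb - gv / br + gv
  er <- 1 - hr - br
  gvm <- hr / er
  gm_alt <- (gvm - gv) * (er / br)
  tibble::tibble(
    freq_hz = grid, Gm = gm, Gm_alt = gm_alt,
    gain = Mod(gm), phase_deg = wrap_deg(Arg(gm) * 180 / pi),
    is_stim = Gv$is_stim,
    valid = ok & Gv$valid & H_over_R_free$valid & B_over_R$valid
  )
}

#' Estimate the mechanosensory transform from externally generated body motion
#'
#' For motor-replay experiments where body motion is imposed and body visual
#' feedback is removed (display co-rotating with the body), the
#' mechanosensory transform follows from the measured B-to-H transform. Two
#' sign conventions are provided: `as_printed` computes
#' `Gm = (1 - Gv) H/B`; `rederived` computes `Gm = (1 + Gv) H/B`, which is
#' what direct re-derivation with `E = -H` gives. Both are returned; the
#' `sign_convention` argument selects which fills the primary `Gm` column.
#'
#' @param Gv `fly_frf`, visual transform.
#' @param H_over_B `fly_frf`, B-to-H transform measured in replay trials.
#' @param sign_convention `"as_printed"` (default) or `"rederived"`.
#' @param coherence_floor Estimates whose `H/B` coherence (if carried in a
#'   `coherence` column) falls below this are flagged low-confidence.
#' @return Tibble with `freq_hz`, complex `Gm`, `Gm_printed`,
#'   `Gm_rederived`, `gain`, `phase_deg`, `is_stim`, `valid`,
#'   `low_confidence`.
#' @export
estimate_Gm_external <- function(Gv, H_over_B,
                                 sign_convention = c("as_printed", "rederived"),
                                 coherence_floor = 0.2) {
  sign_convention <- match.arg(sign_convention)
  grid <- align_frfs(list(Gv, H_over_B))
  gv <- frf_values(Gv); hb <- frf_values(H_over_B)
  gm_printed <- (1 - gv) * hb
  gm_rederived <- (1 + gv) * hb
  gm <- if (sign_convention == "as_printed") gm_printed else gm_rederived
  lowc <- if ("coherence" %in% names(H_over_B)) {
    H_over_B$coherence < coherence_floor
  } else rep(FALSE, length(grid))
  tibble::tibble(
    freq_hz = grid, Gm = gm,
    Gm_printed = gm_printed, Gm_rederived = gm_rederived,
    gain = Mod(gm), phase_deg = wrap_deg(Arg(gm) * 180 / pi),
    is_stim = Gv$is_stim, valid = Gv$valid & H_over_B$valid,
    low_confidence = lowc
  )
}

#' Effective weighting of nested mechanosensory relative to visual feedback
#'
#' Element-wise ratio `GvM / Gv` of the E-to-H transforms measured body-free
#' and body-fixed. Gain 1 and phase 0 at every frequency is the null
#' reference (mechanosensory feedback has no effect); gain below one means
#' the head response per unit sensory error is damped when the body moves.
#'
#' @param GvM `fly_frf`, E-to-H transform, body-free.
#' @param Gv `fly_frf`, E-to-H transform, body-fixed.
#' @param floor Minimum `|Gv|` for a valid ratio.
#' @return A `fly_frf` tibble.
#' @export
feedback_weighting <- function(GvM, Gv, floor = 1e-8) {
  grid <- align_frfs(list(GvM, Gv))
  gvm <- frf_values(GvM); gv <- frf_values(Gv)
  ok <- Mod(gv) >= floor
  new_frf(grid, gvm / gv, Gv$is_stim, ok & GvM$valid & Gv$valid,
          n_flies = attr(GvM, "n_flies"))
}
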