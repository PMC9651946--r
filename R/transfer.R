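#' Continuous-time transfer function in zero-pole-gain form with a pure delay
#'
#' Lightweight container for the rational transforms that make up the gaze
#' stabilization loop. Each transform is `gain * prod(s - zeros) /
#' prod(s - poles) * exp(-delay_s * s)` with `s` the Laplace variable.
#'
#' @param zeros Complex or numeric vector of zeros (rad/s). May be empty.
#' @param poles Complex or numeric vector of poles (rad/s). May be empty.
#' @param gain Scalar gain.
#' @param delay_s Pure transport delay in seconds (>= 0).
#' @return An object of class `tf_zpk`.
#' @examples
#' lp <- tf_zpk(poles = -2 * pi * 5, gain = 2 * pi * 5) # 5 Hz first-order low-pass
#' tf_eval(lp, 5) # half-power point
#' @export
tf_zpk <- function(zeros = numeric(0), poles = numeric(0), gain = 1,
                   delay_s = 0) {
  stopifnot(is.numeric(gain) || is.complex(gain), length(gain) == 1L)
  if (!is.numeric(delay_s) || length(delay_s) != 1L || delay_s < 0) {
    rlang::abort("`delay_s` must be a single non-negative number.")
  }
  if (length(zeros) > length(poles)) {
    rlang::abort("improper transfer function: more zeros than poles.")
  }
  structure(
    list(zeros = as.complex(zeros), poles = as.complex(poles),
         gain = as.numeric(gain), delay_s = delay_s),
    class = "tf_zpk"
  )
}

#' @export
print.tf_zpk <- function(x, ...) {
  cat("<tf_zpk> gain:", format(x$gain, digits = 4),
      " zeros:", length(x$zeros), " poles:", length(x$poles),
      " delay:", format(x$delay_s * 1e3, digits = 3), "ms\n")
  invisible(x)
}

#' Evaluate a continuous transfer function on a frequency grid
#'
#' @param tf A [tf_zpk()] object.
#' @param freq_hz Numeric vector of frequencies in Hz.
#' @return Complex vector, the frequency response at `freq_hz`.
#' @export
tf_eval <- function(tf, freq_hz) {
  stopifnot(inherits(tf, "tf_zpk"))
  s <- 2i * pi * freq_hz
  num <- rep(tf$gain + 0i, length(s))
  for (z in tf$zeros) num <- num * (s - z)
  den <- rep(1 + 0i, length(s))
  for (p in tf$poles) den <- den * (s - p)
  num / den * exp(-tf$delay_s * s)
}

#' Multiply two transfer functions (series connection)
#'
#' Zeros and poles concatenate, gains multiply, delays add. Used to form the
#' sensorimotor transforms as products of a neural controller and the passive
#' biomechanics of the corresponding plant.
#'
#' @param a,b [tf_zpk()] objects.
#' @return A [tf_zpk()] object.
#' @export
tf_mul <- function(a, b) {
  stopifnot(inherits(a, "tf_zpk"), inherits(b, "tf_zpk"))
  tf_zpk(zeros = c(a$zeros, b$zeros), poles = c(a$poles, b$poles),
         gain = a$gain * b$gain, delay_s = a$delay_s + b$delay_s)
}

tf_is_stable <- function(tf) {
  length(tf$poles) == 0L || all(Re(tf$poles) < 0)
}

tf_to_list <- function(tf) {
  list(zeros_re = Re(tf$zeros), zeros_im = Im(tf$zeros),
       poles_re = Re(tf$poles), poles_im = Im(tf$poles),
       gain = tf$gain, delay_s = tf$delay_s)
}

tf_from_list <- function(x) {
  tf_zpk(zeros = complex(real = x$zeros_re, imaginary = x$zeros_im),
         poles = complex(real = x$poles_re, imaginary = x$poles_im),
         gain = x$gain, delay_s = x$delay_s)
}

#' Loop components of the gaze stabilization circuit
#'
#' Bundles the four neural controllers (visual and mechanosensory, for head
#' and body) and the two biomechanical plants that define the nested feedback
#' loop, together with their series products: the visual transform
#' `G_head_V = P_head * C_head_V` (sensory error E to head H), the
#' mechanosensory transform `G_head_M = P_head * C_head_M` (body motion B to
#' head H), and the body analogues.
#'
#' Every component must be open-loop stable; closed-loop stability is checked
#' numerically before any simulation via [check_loop_stability()].
#'
#' @param C_head_V,C_head_M,C_body_V,C_body_M Neural controllers, [tf_zpk()].
#' @param P_head,P_body Biomechanical plants, [tf_zpk()].
#' @return Object of class `loop_components` with elements `C_*`, `P_*`, and
#'   derived `G_head_V`, `G_head_M`, `G_body_V`, `G_body_M`.
#' @seealso [default_fly()], [closed_loop_truth()]
#' @export
loop_components <- function(C_head_V, C_head_M, C_body_V, C_body_M,
                            P_head, P_body) {
  comp <- list(C_head_V = C_head_V, C_head_M = C_head_M,
               C_body_V = C_body_V, C_body_M = C_body_M,
               P_head = P_head, P_body = P_body)
  bad <- names(comp)[!vapply(comp, inherits, logical(1), "tf_zpk")]
  if (length(bad)) {
    rlang::abort(paste0("not tf_zpk objects: ", paste(bad, collapse = ", ")))
  }
  unstable <- names(comp)[!vapply(comp, tf_is_stable, logical(1))]
  if (length(unstable)) {
    rlang::abort(paste0("open-loop unstable components: ",
                        paste(unstable, collapse = ", ")))
  }
  comp$G_head_V <- tf_mul(comp$P_head, comp$C_head_V)
  comp$G_head_M <- tf_mul(comp$P_head, comp$C_head_M)
  comp$G_body_V <- tf_mul(comp$P_body, comp$C_body_V)
  comp$G_body_M <- tf_mul(comp$P_body, comp$C_body_M)
  structure(comp, class = "loop_components")
}

#' @export
print.loop_components <- function(x, ...) {
  cat("<loop_components>\n")
  for (nm in c("G_head_V", "G_head_M", "G_body_V", "G_body_M")) {
    cat(" ", nm, ": ", sep = "")
    print(x[[nm]])
  }
  invisible(x)
}

#' Analytic closed-loop frequency responses of the full loop
#'
#' Solves the loop equations `H = G_head_V E + G_head_M B`,
#' `B = G_body_V E + G_body_M B`, `E = R - H - B` in the frequency domain and
#' returns the exact closed-loop transforms. This is the ground truth that the
#' time-domain simulator and the identification pipeline are checked against.
#'
#' With `Gb' = G_body_V / (1 - G_body_M)` the solution is
#' `E/R = 1 / (1 + G_head_V + Gb' + mech_gate * G_head_M * Gb')`,
#' `H/R = (G_head_V + mech_gate * G_head_M * Gb') * E/R`, `B/R = Gb' * E/R`.
#'
#' @param components A [loop_components()] object.
#' @param freq_hz Frequency grid (Hz).
#' @param mech_gate Scalar in `[0, 1]` multiplying the mechanosensory drive to
#'   the head (1 = self-generated body motion; see [sim_config()]).
#' @param body_fixed If `TRUE`, the body is clamped (`B = 0`) and
#'   `H/R = G_head_V / (1 + G_head_V)`.
#' @return A tibble with columns `freq_hz`, `H_over_R`, `B_over_R`,
#'   `E_over_R`, `G_head_V`, `G_head_M`, `G_head_VM` (all complex). `G_head_VM`
#'   is the E-to-H transform including nested mechanosensory feedback,
#'   `G_head_V + mech_gate * G_head_M * B/E`.
#' @export
closed_loop_truth <- function(components, freq_hz, mech_gate = 1,
                              body_fixed = FALSE) {
  stopifnot(inherits(components, "loop_components"))
  Gv <- tf_eval(components$G_head_V, freq_hz)
  Gm <- mech_gate * tf_eval(components$G_head_M, freq_hz)
  if (body_fixed) {
    H_over_R <- Gv / (1 + Gv)
    B_over_R <- rep(0 + 0i, length(freq_hz))
    E_over_R <- 1 / (1 + Gv)
    GvM <- Gv
  } else {
    Gbv <- tf_eval(components$G_body_V, freq_hz)
    Gbm <- tf_eval(components$G_body_M, freq_hz)
    Gb <- Gbv / (1 - Gbm) # body motion per unit sensory error
    E_over_R <- 1 / (1 + Gv + Gb + Gm * Gb)
    H_over_R <- (Gv + Gm * Gb) * E_over_R
    B_over_R <- Gb * E_over_R
    GvM <- Gv + Gm * Gb
  }
  tibble::tibble(
    freq_hz = freq_hz,
    H_over_R = H_over_R, B_over_R = B_over_R, E_over_R = E_over_R,
    G_head_V = Gv, G_head_M = Gm, G_head_VM = GvM
  )
}

#' Default synthetic fly
#'
#' A documented set of loop components whose closed-loop behavior mirrors the
#' qualitative structure of measured fly gaze stabilization: the body tracks
#' the stimulus like a low-pass filter with gain near one at low frequency;
#' the head visual transform is a modest-gain low-pass with a 30 ms visual
#' delay; the mechanosensory transform from body motion to head is
#' differentiating (high-pass) with a 5 ms haltere delay, and its sign is
#' placed so that the mechanosensory head drive opposes (damps) the visually
#' elicited drive. All numeric values are module constants chosen to produce
#' realistic kinematics, not measured quantities.
#'
#' @return A [loop_components()] object.
#' @examples
#' fly <- default_fly()
#' truth <- closed_loop_truth(fly, c(0.7, 1, 1.5, 2.1, 3.5, 5.3, 10.6))
#' Mod(truth$B_over_R) # low-pass body
#' @export
default_fly <- function() {
  # first-order low-pass 1/(tau s + 1) as zpk
  lp1 <- function(tau, k = 1) tf_zpk(poles = -1 / tau, gain = k / tau)
  loop_components(
    # visual neural controller for the head: low-pass, 30 ms visual delay
    C_head_V = tf_zpk(poles = -1 / 0.05, gain = 0.40 / 0.05, delay_s = 0.030),
    # mechanosensory controller: differentiating (band-limited), 5 ms haltere
    # delay; negative sign -> head drive opposes the visual drive (damping)
    C_head_M = tf_zpk(zeros = 0, poles = c(-1 / 0.008, -1 / 0.008),
                      gain = -0.023 / 0.008^2, delay_s = 0.005),
    # visual controller for the body: larger gain, slower dynamics
    C_body_V = tf_zpk(poles = -1 / 0.30, gain = 8 / 0.30, delay_s = 0.030),
    # body mechanosensory damping (haltere velocity feedback)
    C_body_M = tf_zpk(zeros = 0, poles = c(-1 / 0.05, -1 / 0.005),
                      gain = -0.25 / (0.05 * 0.005), delay_s = 0.005),
    # fast passive neck and slower body biomechanics
    P_head = lp1(0.005),
    P_body = lp1(0.100)
  )
}
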