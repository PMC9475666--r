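# Morphometry: per-individual body measurements and allometrically derived
# quantities (jaw area, mass, VGB length, wetted area).

#' Triangular jaw-area model
#'
#' Models the area between the lower jaws as an isosceles triangle with base
#' the bizygomatic width and height the rostrum-to-blowhole length, scaled by
#' a rotation factor for the outward swing of the mandibles during a lunge:
#' `A_jaw = (W_bz * L_rbh / 2) * O_jaw`.
#'
#' @param W_bz bizygomatic width (m), > 0.
#' @param L_rbh rostrum-to-blowhole length (m), > 0.
#' @param O_jaw dimensionless jaw-rotation factor, >= 1 (default 1.0514,
#'   i.e. a 5.14% outward-rotation offset).
#' @return Jaw area in m^2.
#' @examples
#' jaw_area_triangular(2, 3)            # 3 * 1.0514
#' jaw_area_triangular(2, 3, O_jaw = 1) # plain triangle, 3 m^2
#' @export
jaw_area_triangular <- function(W_bz, L_rbh, O_jaw = 1.0514) {
  if (!is.numeric(W_bz) || any(!is.finite(W_bz)) || any(W_bz <= 0)) {
    stop_domain("W_bz", "bizygomatic width must be finite and > 0")
  }
  if (!is.numeric(L_rbh) || any(!is.finite(L_rbh)) || any(L_rbh <= 0)) {
    stop_domain("L_rbh", "rostrum-to-blowhole length must be finite and > 0")
  }
  if (!is.numeric(O_jaw) || any(!is.finite(O_jaw)) || any(O_jaw < 1)) {
    stop_domain("O_jaw", "jaw-rotation factor must be finite and >= 1")
  }
  (W_bz * L_rbh / 2) * O_jaw
}

#' Generic power-law allometric evaluation
#'
#' Evaluates `a * L_body^b` for a coefficient pair `coeff = c(a = , b = )`.
#'
#' @param L_body body length (m), > 0. Vectorised.
#' @param coeff numeric vector with elements `a` and `b` (or positional).
#' @return `a * L_body^b` in the coefficient's units.
#' @examples
#' allometric_value(10, c(a = 1, b = 2)) # 100
#' @export
allometric_value <- function(L_body, coeff) {
  if (!is.numeric(L_body) || any(!is.finite(L_body)) || any(L_body <= 0)) {
    stop_domain("L_body", "body length must be finite and > 0")
  }
  if (is.null(coeff) || length(coeff) < 2L || any(!is.finite(coeff[1:2]))) {
    stop("allometric coefficients missing or non-finite; check the species entry in the allometry configuration",
         call. = FALSE)
  }
  a <- if (!is.null(names(coeff)) && "a" %in% names(coeff)) coeff[["a"]] else coeff[[1]]
  b <- if (!is.null(names(coeff)) && "b" %in% names(coeff)) coeff[["b"]] else coeff[[2]]
  a * L_body^b
}

#' Complete a morphometric record with derived quantities
#'
#' Fills in the modelled jaw area (when `W_bz` and `L_rbh` are available),
#' allometric body mass, VGB length, and wetted surface area, and records
#' which jaw-area source (direct measurement or triangular model) is active
#' for downstream engulfment calculations. Direct measurement is preferred
#' when present; set `prefer_direct = FALSE` to force the model area.
#'
#' @param individual_id identifier string.
#' @param species one of `"minke"`, `"humpback"`, `"fin"`, `"blue"` (must
#'   have an entry in `config$species`).
#' @param L_body body length (m), required.
#' @param w_max maximum body width (m), optional (`NA` allowed).
#' @param W_bz bizygomatic width (m), optional.
#' @param L_rbh rostrum-to-blowhole length (m), optional.
#' @param A_jaw_direct directly measured jaw area (m^2), optional.
#' @param config an [default_allometry()] object.
#' @param prefer_direct prefer the direct jaw area when both are available.
#' @return Object of class `whale_morphometrics`: a list with the input
#'   fields plus `A_jaw_model`, `A_jaw` (the active area), `jaw_area_method`
#'   (`"direct"` or `"model"`), `M_kg`, `L_VGB`, `S_wet`.
#' @examples
#' m <- complete_morphometrics("bw1", "blue", L_body = 22.3, w_max = 2.9,
#'                             W_bz = 2.9, L_rbh = 5.14)
#' m$M_kg
#' @export
complete_morphometrics <- function(individual_id, species, L_body,
                                   w_max = NA_real_, W_bz = NA_real_,
                                   L_rbh = NA_real_, A_jaw_direct = NA_real_,
                                   config = default_allometry(),
                                   prefer_direct = TRUE) {
  if (!is.numeric(L_body) || !is.finite(L_body) || L_body <= 0) {
    stop_domain("L_body", "body length must be finite and > 0")
  }
  sp <- config$species[[species]]
  if (is.null(sp)) {
    stop(sprintf("no allometric coefficients configured for species '%s'", species),
         call. = FALSE)
  }
  for (f in c("w_max", "W_bz", "L_rbh", "A_jaw_direct")) {
    v <- get(f)
    if (!is.na(v) && (!is.finite(v) || v <= 0)) {
      stop_domain(f, "must be finite and > 0 when supplied")
    }
  }
  if (!is.na(W_bz) && W_bz >= L_body) stop_domain("W_bz", "must be < L_body")
  if (!is.na(L_rbh) && L_rbh >= L_body) stop_domain("L_rbh", "must be < L_body")

  has_model_inputs <- !is.na(W_bz) && !is.na(L_rbh)
  if (!has_model_inputs && is.na(A_jaw_direct)) {
    stop("no jaw-area source: supply either A_jaw_direct or both W_bz and L_rbh",
         call. = FALSE)
  }
  A_jaw_model <- if (has_model_inputs) {
    jaw_area_triangular(W_bz, L_rbh, config$o_jaw)
  } else NA_real_
  method <- if (!is.na(A_jaw_direct) && (prefer_direct || !has_model_inputs)) {
    "direct"
  } else "model"
  A_jaw <- if (method == "direct") A_jaw_direct else A_jaw_model

  structure(list(
    individual_id = individual_id,
    species = species,
    L_body = L_body,
    w_max = w_max,
    W_bz = W_bz,
    L_rbh = L_rbh,
    A_jaw_direct = A_jaw_direct,
    A_jaw_model = A_jaw_model,
    A_jaw = A_jaw,
    jaw_area_method = method,
    M_kg = allometric_value(L_body, sp$mass),
    L_VGB = allometric_value(L_body, sp$vgb),
    S_wet = allometric_value(L_body, sp$swet)
  ), class = "whale_morphometrics")
}

#' @export
print.whale_morphometrics <- function(x, ...) {
  cat(sprintf("<whale_morphometrics> %s (%s)\n", x$individual_id, x$species))
  cat(sprintf("  L_body %.2f m | M %.0f kg | L_VGB %.2f m | S_wet %.1f m^2\n",
              x$L_body, x$M_kg, x$L_VGB, x$S_wet))
  cat(sprintf("  A_jaw %.3f m^2 (%s)\n", x$A_jaw, x$jaw_area_method))
  invisible(x)
}

#' @export
as.data.frame.whale_morphometrics <- function(x, ...) {
  data.frame(individual_id = x$individual_id, species = x$species,
             L_body = x$L_body, w_max = x$w_max, W_bz = x$W_bz,
             L_rbh = x$L_rbh, A_jaw_direct = x$A_jaw_direct,
             A_jaw_model = x$A_jaw_model, A_jaw = x$A_jaw,
             jaw_area_method = x$jaw_area_method, M_kg = x$M_kg,
             L_VGB = x$L_VGB, S_wet = x$S_wet, stringsAsFactors = FALSE)
}

#' Read a morphometrics table from CSV
#'
#' One row per individual; required columns `individual_id`, `species`,
#' `L_body`; optional `w_max`, `W_bz`, `L_rbh`, `A_jaw_direct`. Lines
#' starting with `#` are treated as comments. Returns a list of
#' `whale_morphometrics`.
#'
#' @param path CSV file path.
#' @param config allometry configuration.
#' @param prefer_direct passed to [complete_morphometrics()].
#' @return Named list of `whale_morphometrics` keyed by `individual_id`.
#' @export
read_morphometrics <- function(path, config = default_allometry(),
                               prefer_direct = TRUE) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("individual_id", "species", "L_body")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("morphometrics file missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  opt <- c("w_max", "W_bz", "L_rbh", "A_jaw_direct")
  for (f in opt) if (!f %in% names(df)) df[[f]] <- NA_real_
  out <- lapply(seq_len(nrow(df)), function(i) {
    complete_morphometrics(df$individual_id[i], df$species[i], df$L_body[i],
                           df$w_max[i], df$W_bz[i], df$L_rbh[i],
                           df$A_jaw_direct[i], config, prefer_direct)
  })
  names(out) <- df$individual_id
  out
}
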