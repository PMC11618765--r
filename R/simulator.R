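#' Specification of the synthetic bladder-like phantom
#'
#' Parameters of the synthetic organ used in place of a patient bladder:
#' a stack of smooth convex-ish superellipse slices whose radius follows
#' a smooth axial profile (small near the poles, `max_radius` at the
#' equator), with optional seeded low-frequency radial noise. The
#' defaults emulate a filled bladder on pelvic CT: 28 slices at 3 mm
#' spacing (~8.4 cm axial extent), 40 mm equatorial radius, 64 boundary
#' points per slice.
#'
#' @param n_slices number of slices (>= 3, default 28).
#' @param slice_thickness axial spacing in mm (default 3.0).
#' @param max_radius equatorial radius in mm (default 40).
#' @param points_per_slice boundary points per slice (>= 8, default 64).
#' @param superellipse_exponent shape exponent p in
#'   `(|cos t|^p + |sin t|^p)^(-1/p)`; 2 is a circle, larger values are
#'   squarish (default 2.5, slightly squarish like a filled bladder).
#' @param noise_amp amplitude of low-frequency radial noise in mm
#'   (default 1.0; 0 gives an analytically exact shape).
#' @param seed integer RNG seed for the noise (default 20240).
#' @param axial_profile `"ellipsoid"` (default), `"cylinder"` (constant
#'   radius) or `"sphere"` (`r(z) = sqrt(max_radius^2 - z^2)`; requires
#'   the slice stack to fit inside the sphere).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 28, slice_thickness = 3, max_radius = 40,
                         points_per_slice = 64, superellipse_exponent = 2.5,
                         noise_amp = 1, seed = 20240,
                         axial_profile = c("ellipsoid", "cylinder", "sphere")) {
  axial_profile <- match.arg(axial_profile)
  if (n_slices < 3L) stop("phantom_spec(): 'n_slices' must be >= 3", call. = FALSE)
  if (max_radius <= 0) stop("phantom_spec(): 'max_radius' must be > 0", call. = FALSE)
  if (points_per_slice < 8L) stop("phantom_spec(): 'points_per_slice' must be >= 8",
                                  call. = FALSE)
  if (noise_amp < 0) stop("phantom_spec(): 'noise_amp' must be >= 0", call. = FALSE)
  out <- list(n_slices = as.integer(n_slices),
              slice_thickness = as.numeric(slice_thickness),
              max_radius = as.numeric(max_radius),
              points_per_slice = as.integer(points_per_slice),
              superellipse_exponent = as.numeric(superellipse_exponent),
              noise_amp = as.numeric(noise_amp),
              seed = as.integer(seed),
              axial_profile = axial_profile)
  class(out) <- "phantom_spec"
  out
}

#' Generate the synthetic phantom structure
#'
#' Deterministic given the spec (including its seed): the same spec always
#' yields the same structure. The caller's RNG state is left untouched.
#'
#' @param spec a [phantom_spec].
#' @param name structure name (default "phantom_bladder").
#' @return a `contour_structure`.
#' @export
generate_phantom <- function(spec = phantom_spec(), name = "phantom_bladder") {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_slices
  z <- (seq_len(n) - (n + 1) / 2) * spec$slice_thickness
  radius <- switch(spec$axial_profile,
    cylinder = rep(spec$max_radius, n),
    ellipsoid = {
      a <- (n + 1) / 2 * spec$slice_thickness
      spec$max_radius * sqrt(pmax(0, 1 - (z / a)^2))
    },
    sphere = {
      r2 <- spec$max_radius^2 - z^2
      if (any(r2 <= 0)) {
        stop("generate_phantom(): slice stack does not fit inside the sphere; ",
             "reduce n_slices or slice_thickness", call. = FALSE)
      }
      sqrt(r2)
    })
  theta <- 2 * pi * (seq_len(spec$points_per_slice) - 1L) / spec$points_per_slice
  p <- spec$superellipse_exponent
  shape <- (abs(cos(theta))^p + abs(sin(theta))^p)^(-1 / p)

  noise <- matrix(0, nrow = n, ncol = spec$points_per_slice)
  if (spec$noise_amp > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec$seed)
    # low-frequency (harmonics 2 and 3) radial perturbation, coefficients
    # smooth across slices so adjacent contours look alike
    for (h in 2:3) {
      c_h <- stats::rnorm(1L); s_h <- stats::rnorm(1L)
      phase <- stats::runif(1L, 0, 2 * pi)
      axial <- sin(pi * seq_len(n) / (n + 1) + phase)
      noise <- noise + spec$noise_amp / 2 *
        outer(axial, c_h * cos(h * theta) + s_h * sin(h * theta))
    }
  }

  slices <- lapply(seq_len(n), function(k) {
    r <- pmax(0.2 * radius[k], radius[k] * shape + noise[k, ])
    slice_contour(cbind(r * cos(theta), r * sin(theta)), z = z[k],
                  check_simple = FALSE)
  })
  contour_structure(name, slices, slice_thickness = spec$slice_thickness)
}

#' Shrink a slice contour radially about its centroid
#'
#' Moves every boundary point toward the area centroid by a common factor:
#' `p' = centroid + factor * (p - centroid)`. `factor = 1` returns the
#' contour unchanged; any `factor < 1` displaces every point, so the
#' slice's contribution to the exact-tolerance HSC numerator drops to
#' zero. Area scales as `factor^2`.
#'
#' @param c a `slice_contour`.
#' @param factor scale in (0, 1].
#' @return the shrunk `slice_contour`.
#' @export
shrink_slice <- function(c, factor) {
  stopifnot(inherits(c, "slice_contour"))
  if (!is.numeric(factor) || factor <= 0 || factor > 1) {
    stop("shrink_slice(): 'factor' must be in (0, 1]", call. = FALSE)
  }
  if (factor == 1) return(c)
  cen <- polygon_centroid(c)
  xy <- c$xy
  xy[, 1L] <- cen[1L] + factor * (xy[, 1L] - cen[1L])
  xy[, 2L] <- cen[2L] + factor * (xy[, 2L] - cen[2L])
  out <- slice_contour(xy, z = c$z, check_simple = FALSE)
  attr(out, "orientation") <- attr(c, "orientation")
  out
}

#' Predicted HSC of a contour built from an untouched-slice set
#'
#' When a simulated contour copies the ground-truth contour verbatim on
#' the given slices and shrinks every other slice (factor < 1), its
#' exact-tolerance HSC against the ground truth is exactly the point mass
#' of the untouched slices: sum of their boundary-point counts divided by
#' the total count.
#'
#' @param gt ground-truth `contour_structure`.
#' @param untouched_slices integer slice indices left untouched.
#' @return predicted HSC in \[0, 1\].
#' @export
hsc_from_untouched <- function(gt, untouched_slices) {
  counts <- vapply(gt$slices, function(s) nrow(s$xy), integer(1L))
  if (length(untouched_slices) &&
      (any(untouched_slices < 1L) || any(untouched_slices > length(counts)))) {
    stop("hsc_from_untouched(): slice index out of range", call. = FALSE)
  }
  sum(counts[untouched_slices]) / sum(counts)
}

#' Choose the untouched-slice set closest to a target HSC
#'
#' Accumulates slices from the poles inward (smallest-area slices first,
#' ties broken toward the lower slice index) and returns the prefix whose
#' point mass is closest to `hsc_target`. Growing from the poles keeps the
#' untouched volume share minimal, which keeps the achievable-DSC floor of
#' the shrink construction low; achievable HSC values are granular in
#' multiples of one slice's point mass.
#'
#' @param gt ground-truth `contour_structure`.
#' @param hsc_target target HSC in \[0, 1\].
#' @return integer vector of untouched slice indices (possibly empty).
#' @export
select_untouched_slices <- function(gt, hsc_target) {
  stopifnot(hsc_target >= 0, hsc_target <= 1)
  areas <- vapply(gt$slices, polygon_area, numeric(1L))
  ord <- order(areas, seq_along(areas))  # smallest first, lower index on ties
  counts <- vapply(gt$slices, function(s) nrow(s$xy), integer(1L))
  mass <- cumsum(counts[ord]) / sum(counts)
  errs <- abs(c(0, mass) - hsc_target)
  k <- which.min(errs) - 1L
  if (k == 0L) integer(0) else sort(ord[seq_len(k)])
}

#' Assemble a simulated contour from an untouched set and a shrink factor
#'
#' @param gt ground-truth `contour_structure`.
#' @param untouched integer slice indices copied verbatim.
#' @param factor radial shrink factor in (0, 1] applied to all other slices.
#' @param name output structure name.
#' @return a `contour_structure`.
#' @export
build_simulated_contour <- function(gt, untouched, factor, name = "simulated") {
  slices <- lapply(seq_along(gt$slices), function(k) {
    if (k %in% untouched) gt$slices[[k]] else shrink_slice(gt$slices[[k]], factor)
  })
  contour_structure(name, slices, slice_thickness = gt$slice_thickness)
}

#' Solve for the shrink factor that achieves a target DSC
#'
#' The volumetric DSC between ground truth and a contour built by
#' shrinking the non-untouched slices is continuous and strictly
#' increasing in the shrink factor, from a floor of `2U/(T + U)` as the
#' factor approaches 0 (U, T: untouched and total mask voxel counts) up
#' to 1 at factor 1. The factor achieving `dsc_target` is found by
#' bisection on (0, 1], replacing the manual trial-and-error editing such
#' contour sets were originally built with.
#'
#' @param gt ground-truth `contour_structure`.
#' @param untouched integer slice indices left untouched.
#' @param dsc_target target DSC; must exceed the floor.
#' @param g a `raster_grid` (default: 1 mm grid over `gt`).
#' @param tol DSC tolerance for convergence (default 0.005).
#' @param max_iter maximum bisection iterations (default 60).
#' @return list with `factor`, `achieved_dsc`, `floor`, `iterations`.
#' @export
solve_shrink_for_dsc <- function(gt, untouched, dsc_target, g = NULL,
                                 tol = 0.005, max_iter = 60L) {
  stopifnot(dsc_target > 0, dsc_target <= 1, tol > 0)
  if (is.null(g)) g <- default_grid(gt)
  n <- length(gt$slices)
  untouched <- sort(unique(as.integer(untouched)))
  modified <- setdiff(seq_len(n), untouched)

  if (!length(modified)) {
    if (abs(dsc_target - 1) > tol) {
      stop("solve_shrink_for_dsc(): all slices untouched forces DSC = 1, ",
           "cannot reach ", dsc_target, call. = FALSE)
    }
    return(list(factor = 1, achieved_dsc = 1, floor = 1, iterations = 0L))
  }

  gt_masks <- lapply(gt$slices, rasterize_slice, g = g)
  gt_counts <- vapply(gt_masks, sum, numeric(1L))
  total <- sum(gt_counts)
  u_count <- sum(gt_counts[untouched])
  floor_dsc <- 2 * u_count / (total + u_count)
  if (dsc_target <= floor_dsc) {
    stop(sprintf(paste0("solve_shrink_for_dsc(): target %.3f is at or below the ",
                        "achievable floor %.3f imposed by the untouched slices"),
                 dsc_target, floor_dsc), call. = FALSE)
  }

  dsc_at <- function(f) {
    inter <- u_count
    b_count <- u_count
    for (k in modified) {
      m <- rasterize_slice(shrink_slice(gt$slices[[k]], f), g)
      b_count <- b_count + sum(m)
      inter <- inter + sum(m & gt_masks[[k]])
    }
    2 * inter / (total + b_count)
  }

  if (dsc_target == 1) {
    return(list(factor = 1, achieved_dsc = 1, floor = floor_dsc,
                iterations = 0L))
  }
  lo <- 1e-6; hi <- 1
  best <- NULL
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    d <- dsc_at(mid)
    if (is.null(best) || abs(d - dsc_target) < abs(best$achieved_dsc - dsc_target)) {
      best <- list(factor = mid, achieved_dsc = d, floor = floor_dsc,
                   iterations = it)
    }
    if (abs(d - dsc_target) <= tol / 2) break
    if (d < dsc_target) lo <- mid else hi <- mid
  }
  best$iterations <- it
  best
}

#' Define a simulation target set
#'
#' @param mode `"fixed_dsc"` (one common DSC, a sweep of HSC targets) or
#'   `"fixed_hsc"` (one common HSC, a sweep of DSC targets).
#' @param fixed_value the common metric value, in (0, 1].
#' @param sweep_values the swept metric targets, each in (0, 1] for DSC
#'   sweeps or \[0, 1\] for HSC sweeps; sorted ascending.
#' @param tol metric tolerance for the bisection (default 0.005).
#' @return an object of class `sim_target`.
#' @export
sim_target <- function(mode = c("fixed_dsc", "fixed_hsc"), fixed_value,
                       sweep_values, tol = 0.005) {
  mode <- match.arg(mode)
  stopifnot(fixed_value > 0, fixed_value <= 1, tol > 0,
            all(sweep_values >= 0), all(sweep_values <= 1))
  out <- list(mode = mode, fixed_value = as.numeric(fixed_value),
              sweep_values = sort(as.numeric(sweep_values)),
              tol = as.numeric(tol))
  class(out) <- "sim_target"
  out
}

#' Targets of the first simulated contour set
#'
#' Five contours sharing DSC 0.850 with HSC targets 0, 0.111, 0.295,
#' 0.507 and 0.704.
#' @param tol bisection DSC tolerance.
#' @return a [sim_target].
#' @export
set1_targets <- function(tol = 0.005) {
  sim_target("fixed_dsc", 0.850, c(0, 0.111, 0.295, 0.507, 0.704), tol)
}

#' Targets of the second simulated contour set
#'
#' Seven contours sharing HSC 0.464 with DSC targets 0.640, 0.730, 0.765,
#' 0.805, 0.849, 0.899 and 0.953.
#' @param tol bisection DSC tolerance.
#' @return a [sim_target].
#' @export
set2_targets <- function(tol = 0.005) {
  sim_target("fixed_hsc", 0.464,
             c(0.640, 0.730, 0.765, 0.805, 0.849, 0.899, 0.953), tol)
}

#' Build a contour set with one common DSC and a sweep of HSCs
#'
#' For each HSC target, chooses the untouched-slice set whose point mass
#' is closest to the target ([select_untouched_slices]), then bisects the
#' shrink factor of the remaining slices so the volumetric DSC hits the
#' common value ([solve_shrink_for_dsc]). Achieved values are verified by
#' recomputing [hsc()] and [dsc()] on the outputs.
#'
#' An HSC target of 1 combined with a fixed DSC below 1 is infeasible
#' (untouching everything forces DSC = 1) and raises an error.
#'
#' @param gt ground-truth `contour_structure`.
#' @param target a [sim_target] with mode `"fixed_dsc"`; sweep values are
#'   HSC targets, `fixed_value` the common DSC.
#' @param g a `raster_grid` (default 1 mm over `gt`).
#' @return an object of class `sim_set`: list of case records, each with
#'   `structure`, `target_hsc`/`target_dsc`, `achieved_hsc`,
#'   `achieved_dsc`, `factor`, `untouched`.
#' @export
build_fixed_dsc_set <- function(gt, target = set1_targets(), g = NULL) {
  stopifnot(inherits(target, "sim_target"), target$mode == "fixed_dsc")
  if (is.null(g)) g <- default_grid(gt)
  cases <- lapply(seq_along(target$sweep_values), function(i) {
    h <- target$sweep_values[i]
    if (h >= 1 && target$fixed_value < 1) {
      stop("build_fixed_dsc_set(): HSC target 1 forces DSC = 1, ",
           "incompatible with fixed DSC ", target$fixed_value, call. = FALSE)
    }
    untouched <- select_untouched_slices(gt, h)
    sol <- solve_shrink_for_dsc(gt, untouched, target$fixed_value, g,
                                tol = target$tol)
    built <- build_simulated_contour(gt, untouched, sol$factor,
                                     name = sprintf("set1_case%d", i))
    list(structure = built,
         target_hsc = h, target_dsc = target$fixed_value,
         achieved_hsc = hsc(built, gt)$value,
         achieved_dsc = dsc(built, gt, g)$value,
         factor = sol$factor, untouched = untouched)
  })
  class(cases) <- "sim_set"
  attr(cases, "mode") <- "fixed_dsc"
  cases
}

#' Build a contour set with one common HSC and a sweep of DSCs
#'
#' One untouched-slice set (closest achievable to the common HSC) is fixed
#' for all cases; for each DSC target the shrink factor of the remaining
#' slices is bisected. All cases share the same untouched set, hence
#' exactly the same measured HSC. DSC targets at or below the floor
#' imposed by the untouched slices raise an infeasibility error.
#'
#' @param gt ground-truth `contour_structure`.
#' @param target a [sim_target] with mode `"fixed_hsc"`; sweep values are
#'   DSC targets, `fixed_value` the common HSC.
#' @param g a `raster_grid` (default 1 mm over `gt`).
#' @return a `sim_set` (see [build_fixed_dsc_set]).
#' @export
build_fixed_hsc_set <- function(gt, target = set2_targets(), g = NULL) {
  stopifnot(inherits(target, "sim_target"), target$mode == "fixed_hsc")
  if (is.null(g)) g <- default_grid(gt)
  untouched <- select_untouched_slices(gt, target$fixed_value)
  cases <- lapply(seq_along(target$sweep_values), function(i) {
    d <- target$sweep_values[i]
    sol <- solve_shrink_for_dsc(gt, untouched, d, g, tol = target$tol)
    built <- build_simulated_contour(gt, untouched, sol$factor,
                                     name = sprintf("set2_case%d", i))
    list(structure = built,
         target_hsc = target$fixed_value, target_dsc = d,
         achieved_hsc = hsc(built, gt)$value,
         achieved_dsc = dsc(built, gt, g)$value,
         factor = sol$factor, untouched = untouched)
  })
  class(cases) <- "sim_set"
  attr(cases, "mode") <- "fixed_hsc"
  cases
}

#' Manifest of a simulated contour set
#'
#' @param set a `sim_set`.
#' @return data.frame with one row per case: targets, achieved metrics,
#'   shrink factor and the untouched slice indices.
#' @export
sim_manifest <- function(set) {
  stopifnot(inherits(set, "sim_set"))
  do.call(rbind, lapply(seq_along(set), function(i) {
    cs <- set[[i]]
    data.frame(case = i, mode = attr(set, "mode"),
               target_hsc = cs$target_hsc, target_dsc = cs$target_dsc,
               achieved_hsc = cs$achieved_hsc, achieved_dsc = cs$achieved_dsc,
               factor = cs$factor,
               untouched = paste(cs$untouched, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
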