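# Synthetic head-and-neck phantoms: ellipsoidal anatomy with nested target
# volumes, disjoint OAR blobs, and a reference dose built from a logistic
# falloff of the signed distance to the PTV surface. The cohort generator is
# the package's fully reproducible stand-in for clinical planning data.

#' Phantom specification
#'
#' Parameters of the synthetic head-and-neck generator. Defaults are sized for
#' desk-scale work: a 64 x 64 x 32 grid at 2 mm isotropic spacing, 70 Gy
#' prescription, and a dose model calibrated so that ground-truth PTV coverage
#' and homogeneity land in the clinical range (D95 above 0.95 of prescription,
#' H1 below 0.1).
#'
#' @param grid_shape integer length-3 voxel grid.
#' @param spacing mm per axis.
#' @param seed integer; every stochastic step derives from it.
#' @param n_oars number of disjoint organ-at-risk blobs.
#' @param prescription prescription dose in Gy.
#' @param ptv_radius_range mm; PTV semi-axes are drawn from this range with
#'   per-axis jitter.
#' @param falloff_tau mm; logistic dose-gradient scale outside the PTV.
#' @param oar_sparing fraction in `[0, 1]` by which dose is suppressed inside
#'   (blurred) OARs.
#' @param noise_sd additive Gaussian noise on the reference dose, Gy.
#' @param hotspot peak dose as a fraction of prescription (a modest clinical
#'   hot spot; keeps the prescription isodose surface wrapped tightly around
#'   the PTV).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 32), spacing = c(2, 2, 2),
                         seed = 1L, n_oars = 4L, prescription = 70,
                         ptv_radius_range = c(16, 24), falloff_tau = 2,
                         oar_sparing = 0.3, noise_sd = 0.5, hotspot = 1.05) {
  stopifnot(prescription > 0, falloff_tau > 0,
            oar_sparing >= 0, oar_sparing <= 1, noise_sd >= 0,
            length(grid_shape) == 3, all(grid_shape >= 8))
  structure(list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
                 seed = as.integer(seed), n_oars = as.integer(n_oars),
                 prescription = prescription, ptv_radius_range = ptv_radius_range,
                 falloff_tau = falloff_tau, oar_sparing = oar_sparing,
                 noise_sd = noise_sd, hotspot = hotspot),
            class = "phantom_spec")
}

# Run code under a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  code
}

# Voxelized ellipsoid: center and semi-axes in mm on the case grid.
ellipsoid_mask <- function(grid_shape, spacing, center, semi) {
  ax <- lapply(1:3, function(a) {
    coord <- (seq_len(grid_shape[a]) - 0.5) * spacing[a]
    ((coord - center[a]) / semi[a])^2
  })
  r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  (r2 <= 1) * 1
}

# Separable Gaussian blur with sigma in voxels, via per-axis band matrices.
gauss_blur <- function(v, sigma) {
  if (sigma <= 0) return(v)
  K <- max(1L, ceiling(3 * sigma))
  w <- exp(-0.5 * ((-K:K) / sigma)^2)
  for (axis in 1:3) {
    d <- dim(v)
    n <- d[axis]
    B <- matrix(0, n, n)
    for (off in -K:K) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      B[cbind(i[ok], j[ok])] <- w[off + K + 1]
    }
    B <- B / rowSums(B)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(v, perm), nrow = n)
    v <- aperm(array(B %*% m, c(n, d[perm[2]], d[perm[3]])), order(perm))
  }
  v
}

oar_name_bank <- c("spinal_cord", "parotid_l", "parotid_r", "larynx",
                   "mandible", "esophagus", "oral_cavity", "brain_stem")

#' Generate phantom anatomy
#'
#' Builds an ellipsoidal "head" CT with air/tissue/bone intensity bands,
#' nested GTV within CTV within PTV target ellipsoids, and `n_oars` disjoint
#' OAR blobs placed inside the head but outside the PTV. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `ct` (3D array) and `structures` ([structure_set()]).
#' @export
generate_anatomy <- function(spec) {
  gs <- spec$grid_shape; sp <- spec$spacing
  extent <- gs * sp
  with_seed(spec$seed, {
    head_center <- extent / 2
    head_semi <- extent * c(0.42, 0.45, 0.60)
    head <- ellipsoid_mask(gs, sp, head_center, head_semi)
    shell <- head - ellipsoid_mask(gs, sp, head_center, head_semi * 0.88)
    ct <- array(-1000, gs)
    ct[head == 1] <- 40
    ct <- ct + head * array(rnorm(prod(gs), 0, 15), gs)
    ct[shell == 1] <- 700

    margin <- 2 * max(sp)
    ptv <- NULL
    for (try in 1:50) {
      semi <- runif(3, spec$ptv_radius_range[1], spec$ptv_radius_range[2]) *
        runif(3, 0.85, 1.15)
      center <- head_center + runif(3, -0.3, 0.3) * head_semi
      inner <- ellipsoid_mask(gs, sp, center, semi + margin)
      # PTV plus margin must sit inside the head and off the grid boundary
      bound_ok <- all(center - semi - margin > 0) && all(center + semi + margin < extent)
      if (bound_ok && all(head[inner == 1] == 1)) {
        ptv <- ellipsoid_mask(gs, sp, center, semi)
        break
      }
    }
    if (is.null(ptv) || sum(ptv) < 8)
      stop("generation error: could not place a PTV inside the head")
    ctv <- ellipsoid_mask(gs, sp, center, semi * 0.70)
    gtv <- ellipsoid_mask(gs, sp, center, semi * 0.45)

    masks <- list(PTV = ptv, CTV = ctv, GTV = gtv)
    occupied <- ptv
    placed <- 0L
    for (i in seq_len(spec$n_oars)) {
      ok <- FALSE
      for (try in 1:200) {
        osemi <- runif(3, 5, 11)
        ocen <- head_center + runif(3, -0.75, 0.75) * head_semi
        m <- ellipsoid_mask(gs, sp, ocen, osemi)
        if (sum(m) >= 4 && all(head[m == 1] == 1) && sum(m * occupied) == 0) {
          masks[[oar_name_bank[i]]] <- m
          occupied <- pmin(occupied + m, 1)
          ok <- TRUE; placed <- placed + 1L
          break
        }
      }
      if (!ok) stop("generation error: could not place OAR ", i, " after 200 retries")
    }
    roles <- setNames(c("target", "target", "target", rep("oar", placed)), names(masks))
    list(ct = ct, structures = structure_set(masks, roles))
  })
}

# Signed Euclidean distance (mm) to the mask surface: negative inside.
signed_distance <- function(mask, spacing) {
  d_out <- sqrt(cpp_edt_sq(mask, spacing))
  d_in <- sqrt(cpp_edt_sq(1 - mask, spacing))
  d_out - d_in
}

#' Generate a phantom reference dose
#'
#' The reference dose is a logistic falloff of the signed distance to the PTV
#' surface: `D(x) = hotspot * Rx * s((-dist(x) + 2.5 * tau) / tau)`, with `s`
#' the logistic function and `dist` negative inside the PTV. The midpoint of
#' the falloff sits 2.5 gradient-scales outside the PTV surface, so the whole
#' PTV interior receives close to the (slightly hot) prescription while dose
#' far from the target decays to zero. Inside (Gaussian-blurred) OAR masks the
#' dose is multiplicatively suppressed by `oar_sparing`, and i.i.d. Gaussian
#' noise of `noise_sd` Gy is added before clipping at zero. Deterministic
#' given `spec$seed`.
#'
#' @param structures a [structure_set()] containing a `PTV`.
#' @param spec a [phantom_spec()].
#' @return A [dose_volume()] in Gy.
#' @export
generate_reference_dose <- function(structures, spec) {
  if (!"PTV" %in% names(structures$masks))
    stop("invalid argument: structures must contain a PTV")
  ptv <- structures$masks$PTV
  dist <- signed_distance(ptv, spec$spacing)
  tau <- spec$falloff_tau
  dose <- spec$hotspot * spec$prescription * plogis((-dist + 2.5 * tau) / tau)
  if (spec$oar_sparing > 0) {
    oars <- names(structures$roles)[structures$roles == "oar"]
    if (length(oars) > 0) {
      soft <- Reduce(`+`, structures$masks[oars])
      soft <- gauss_blur(pmin(soft, 1), sigma = 3)
      if (max(soft) > 0) soft <- soft / max(soft)
      dose <- dose * (1 - spec$oar_sparing * soft)
    }
  }
  if (spec$noise_sd > 0) {
    dose <- dose + with_seed(spec$seed + 500017L,
                             array(rnorm(length(dose), 0, spec$noise_sd), dim(dose)))
  }
  dose_volume(pmax(dose, 0), spacing = spec$spacing)
}

#' Generate a phantom cohort
#'
#' Independent cases with per-case seeds `spec$seed + i`, each a complete
#' [plan_case()] (CT, structures, reference dose, prescription).
#'
#' @param spec a [phantom_spec()].
#' @param n_cases number of cases, `>= 1`.
#' @return A list of [plan_case()] objects.
#' @export
generate_cohort <- function(spec, n_cases) {
  stopifnot(n_cases >= 1)
  lapply(seq_len(n_cases), function(i) {
    cs <- spec
    cs$seed <- spec$seed + i
    anat <- generate_anatomy(cs)
    dose <- generate_reference_dose(anat$structures, cs)
    plan_case(anat$ct, anat$structures, dose, prescription = spec$prescription,
              case_id = sprintf("phantom_%04d", i), spacing = spec$spacing)
  })
}
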