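# Synthetic specimen generator: parametric fish-like silhouettes rendered to
# grayscale images, with 14 named landmarks tied to the outline geometry,
# class-dependent localized shape effects, injectable class-correlated
# technical artifacts, and exact ground-truth masks.
#
# Coordinate convention (used package-wide): pixel coordinates are 0-based,
# (x = column, y = row), origin at the top-left of the image.  Images are
# stored as numeric matrices indexed [row + 1, col + 1] with values in [0, 1].

#' Landmark acronyms
#'
#' The 14 standard fish-morphometry landmarks used throughout the package, in
#' their canonical order: upper tip of snout (UTP), center of eye (EYE),
#' anterior/posterior insertion of the dorsal fin (AOD, POD), dorsal/ventral
#' insertion of the caudal fin (DIC, VOC), posterior insertion of the anal fin
#' (PIA), dorsal base of the pectoral fin (BPF), posterior/ventral edge of the
#' operculum (PEO, VEO), anterior insertion of the anal fin (AOA), anterior
#' insertion of the pelvic fin (AOP), midpoint of the caudal insertions (HCF)
#' and posterior end of the mouth (EMO).
#'
#' @return Character vector of length 14.
#' @export
landmark_acronyms <- function() {
  c("UTP", "EYE", "AOD", "POD", "DIC", "VOC", "PIA",
    "BPF", "PEO", "VEO", "AOA", "AOP", "HCF", "EMO")
}

ms_stop <- function(msg, class = "morphsal_error", call. = FALSE) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Describe a class-dependent shape effect
#'
#' @param region One of `"dorsal"`, `"belly"`, `"snout"`, `"caudal"` naming the
#'   body region that is deformed.
#' @param classes Integer vector of affected class ids (0-based).
#' @param amplitude Deformation amplitude in pixels; scalar or one value per
#'   affected class.
#' @return A list describing the effect, for use in [synth_spec()].
#' @export
effect_region <- function(region, classes, amplitude) {
  region <- match.arg(region, c("dorsal", "belly", "snout", "caudal"))
  if (!all(is.finite(amplitude)))
    ms_stop("effect amplitudes must be finite", "morphsal_config_error")
  amplitude <- rep_len(amplitude, length(classes))
  list(region = region, classes = as.integer(classes), amplitude = amplitude)
}

#' Describe an injectable technical artifact
#'
#' @param kind One of `"background-gradient"`, `"pin-blob"`, `"dirt-specks"`.
#' @param prob Per-class Bernoulli presence probability; scalar or one value
#'   per class.  Probability 1 for one class and 0 elsewhere yields a
#'   perfectly label-confounded artifact.
#' @param intensity Additive grayscale intensity of the artifact (may be
#'   negative for dark artifacts).
#' @return A list describing the artifact, for use in [synth_spec()].
#' @export
artifact <- function(kind, prob, intensity) {
  kind <- match.arg(kind, c("background-gradient", "pin-blob", "dirt-specks"))
  if (any(prob < 0 | prob > 1))
    ms_stop("artifact probabilities must lie in [0, 1]", "morphsal_config_error")
  list(kind = kind, prob = prob, intensity = intensity)
}

#' Specification of a synthetic dataset
#'
#' Defines the study conditions for [generate_dataset()]: per-class sample
#' counts (defaulting to the unbalanced six-lake design 36/38/31/26/38/40),
#' image resolution, shape effects, technical artifacts and noise levels.
#'
#' @param n_per_class Integer vector of per-class specimen counts.
#' @param image_side Image side length in pixels (square images); >= 32.
#' @param effect_regions List of [effect_region()] descriptions.  The default
#'   is a dorsal deformation whose amplitude grows linearly over the classes
#'   up to 5 px, emulating a graded population-specific morphotype.
#' @param artifact_spec List of [artifact()] descriptions (default none).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise, in
#'   grayscale units on the [0, 1] scale.
#' @param jitter_sd Within-class variability control, in pixels: standard
#'   deviation of the individual geometric jitter; also scales the random
#'   pose (translation/scale/rotation) and the landmark annotation noise.
#'   Set to 0 for perfectly repeatable specimens.
#' @param seed Integer seed; regeneration with the same spec and seed is
#'   bit-identical.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_per_class = c(36L, 38L, 31L, 26L, 38L, 40L),
                       image_side = 64L,
                       effect_regions = list(
                         effect_region("dorsal", 0:(length(n_per_class) - 1),
                                       seq(0, 5, length.out = length(n_per_class)))),
                       artifact_spec = list(),
                       noise_sd = 0.02,
                       jitter_sd = 0.75,
                       seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (any(n_per_class < 1L))
    ms_stop("each class needs at least one specimen", "morphsal_config_error")
  if (image_side < 32L)
    ms_stop("image_side must be at least 32", "morphsal_config_error")
  C <- length(n_per_class)
  for (ef in effect_regions) {
    if (any(ef$classes < 0L) || any(ef$classes >= C))
      ms_stop("effect classes out of range", "morphsal_config_error")
    if (!all(is.finite(ef$amplitude)))
      ms_stop("effect amplitudes must be finite", "morphsal_config_error")
  }
  for (af in artifact_spec) {
    if (any(af$prob < 0 | af$prob > 1))
      ms_stop("artifact probabilities must lie in [0, 1]", "morphsal_config_error")
  }
  if (noise_sd < 0 || jitter_sd < 0)
    ms_stop("noise_sd and jitter_sd must be nonnegative", "morphsal_config_error")
  structure(list(n_per_class = n_per_class, image_side = as.integer(image_side),
                 n_landmarks = 14L, effect_regions = effect_regions,
                 artifact_spec = artifact_spec, noise_sd = noise_sd,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "synth_spec")
}

# Base fish geometry for a given image side, before effects and jitter.
# All lengths in pixels; the fish frame is centered on the body with x
# pointing toward the tail and y pointing down (image convention).
base_geometry <- function(S) {
  list(cx = 0.42 * S, cy = 0.52 * S,
       a = 0.26 * S,           # rear body semi-axis
       a_snout = 0.26 * S,     # frontal semi-axis (snout effect adds here)
       b_top = 0.14 * S,       # dorsal semi-axis
       b_belly = 0.14 * S,     # ventral semi-axis (belly effect adds here)
       h_dorsal = 0.10 * S,    # dorsal fin height above the back
       hump = 0,               # dorsal hump amplitude (dorsal effect)
       tail_shift = 0,         # caudal insertion shift (caudal effect)
       dx = 0, dy = 0, logscale = 0, theta = 0)
}

apply_effect <- function(geom, region, amplitude) {
  switch(region,
         dorsal = { geom$hump <- geom$hump + amplitude },
         belly  = { geom$b_belly <- geom$b_belly + amplitude },
         snout  = { geom$a_snout <- geom$a_snout + amplitude },
         caudal = { geom$tail_shift <- geom$tail_shift + amplitude })
  geom
}

# Dorsal hump height profile along the back (fish-frame x), peaking at the
# anterior dorsal-fin insertion so that AOD carries most of the deformation.
hump_profile <- function(x, geom) {
  xd1 <- -0.45 * geom$a
  geom$hump * exp(-((x - xd1)^2) / (2 * (0.25 * geom$a)^2))
}

# Outline helpers in the fish frame (y negative = dorsal side).
y_back <- function(x, geom) {
  ax <- ifelse(x < 0, geom$a_snout, geom$a)
  r2 <- pmax(0, 1 - (x / ax)^2)
  -geom$b_top * sqrt(r2)
}
y_belly <- function(x, geom) {
  ax <- ifelse(x < 0, geom$a_snout, geom$a)
  r2 <- pmax(0, 1 - (x / ax)^2)
  geom$b_belly * sqrt(r2)
}

# 14 landmarks in the fish frame, tied to the parametric outline.
fish_landmarks <- function(geom) {
  a <- geom$a; as_ <- geom$a_snout; bt <- geom$b_top; bb <- geom$b_belly
  xd1 <- -0.45 * a; xd2 <- 0.35 * a
  xc0 <- 0.88 * a + geom$tail_shift
  xa1 <- 0.15 * a; xa2 <- 0.55 * a
  xp1 <- -0.35 * a
  lm <- rbind(
    UTP = c(-as_ * cos(10 * pi / 180), -bt * sin(10 * pi / 180)),
    EYE = c(-0.70 * a, -0.25 * bt),
    AOD = c(xd1, y_back(xd1, geom) - hump_profile(xd1, geom)),
    POD = c(xd2, y_back(xd2, geom) - hump_profile(xd2, geom)),
    DIC = c(xc0, -0.36 * bt),
    VOC = c(xc0, 0.36 * bb),
    PIA = c(xa2, y_belly(xa2, geom)),
    BPF = c(-0.45 * a, 0.10 * bb),
    PEO = c(-0.07 * a, 0),
    VEO = c(-0.35 * a + 0.28 * a * cos(70 * pi / 180),
            0.28 * a * sin(70 * pi / 180)),
    AOA = c(xa1, y_belly(xa1, geom)),
    AOP = c(xp1, y_belly(xp1, geom)),
    HCF = c(xc0, (-0.36 * bt + 0.36 * bb) / 2),
    EMO = c(-0.80 * as_, 0.18 * bb))
  lm
}

in_polygon <- function(px, py, poly) {
  # even-odd rule, vectorized over points; poly is a 2-column matrix
  nv <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Render one specimen: returns list(img, fish_mask) with the silhouette mask
# (fish pixels incl. fins) used for artifact placement.  Rasterization uses
# hard region tests (no anti-aliasing) so difference masks are exact.
render_fish <- function(geom, S) {
  xs <- rep(0:(S - 1), each = S)    # x = column, varying slowly
  ys <- rep(0:(S - 1), times = S)   # y = row, varying fast (column-major)
  sc <- exp(geom$logscale); th <- geom$theta
  # world -> fish frame
  xr <- (xs - geom$cx - geom$dx); yr <- (ys - geom$cy - geom$dy)
  xf <- (cos(th) * xr + sin(th) * yr) / sc
  yf <- (-sin(th) * xr + cos(th) * yr) / sc

  a <- geom$a; as_ <- geom$a_snout; bt <- geom$b_top; bb <- geom$b_belly
  ax <- ifelse(xf < 0, as_, a)
  by <- ifelse(yf < 0, bt, bb)
  body <- (xf / ax)^2 + (yf / by)^2 <= 1
  # dorsal hump: band between humped and plain back outline
  hp <- hump_profile(xf, geom)
  yb <- y_back(xf, geom)
  hump <- (abs(xf) < a) & (hp > 0) & (yf <= yb) & (yf >= yb - hp)
  body <- body | hump

  xd1 <- -0.45 * a; xd2 <- 0.35 * a
  yb1 <- y_back(xd1, geom) - hump_profile(xd1, geom)
  yb2 <- y_back(xd2, geom) - hump_profile(xd2, geom)
  dorsal <- rbind(c(xd1, yb1),
                  c(xd1 + 0.10 * a, yb1 - geom$h_dorsal),
                  c(xd2, yb2 - 0.45 * geom$h_dorsal),
                  c(xd2, yb2))
  xc0 <- 0.88 * a + geom$tail_shift
  caudal <- rbind(c(xc0, -0.36 * bt),
                  c(xc0 + 0.50 * a, -0.55 * bt),
                  c(xc0 + 0.50 * a, 0.55 * bb),
                  c(xc0, 0.36 * bb))
  xa1 <- 0.15 * a; xa2 <- 0.55 * a
  anal <- rbind(c(xa1, y_belly(xa1, geom)),
                c(xa2, y_belly(xa2, geom)),
                c(0.45 * a, y_belly(0.45 * a, geom) + 0.45 * bb))
  xp1 <- -0.35 * a; xp2 <- -0.10 * a
  pelvic <- rbind(c(xp1, y_belly(xp1, geom)),
                  c(xp2, y_belly(xp2, geom)),
                  c(-0.15 * a, y_belly(-0.15 * a, geom) + 0.40 * bb))
  fins <- in_polygon(xf, yf, dorsal) | in_polygon(xf, yf, caudal) |
    in_polygon(xf, yf, anal) | in_polygon(xf, yf, pelvic)

  pect <- in_polygon(xf, yf, rbind(c(-0.45 * a, 0.10 * bb),
                                   c(-0.15 * a, 0.25 * bb),
                                   c(-0.35 * a, 0.55 * bb)))
  eye <- (xf + 0.70 * a)^2 + (yf + 0.25 * bt)^2 <= (0.18 * bt)^2
  opd <- sqrt((xf + 0.35 * a)^2 + yf^2)
  operc <- body & abs(opd - 0.28 * a) <= 0.035 * a & xf > -0.35 * a
  # mouth: short segment from snout tip toward EMO
  m0 <- c(-0.98 * as_, 0.06 * bb); m1 <- c(-0.80 * as_, 0.18 * bb)
  mseg <- m1 - m0
  tseg <- pmin(1, pmax(0, ((xf - m0[1]) * mseg[1] + (yf - m0[2]) * mseg[2]) /
                         sum(mseg^2)))
  dseg <- sqrt((xf - (m0[1] + tseg * mseg[1]))^2 +
                 (yf - (m0[2] + tseg * mseg[2]))^2)
  mouth <- body & dseg <= 0.7

  img <- rep(0.08, S * S)
  img[fins] <- 0.55
  img[body] <- 0.75
  img[pect & body] <- 0.45
  img[operc] <- 0.35
  img[mouth] <- 0.30
  img[eye] <- 0.15
  list(img = matrix(img, nrow = S),          # [row, col] = [y + 1, x + 1]
       fish = matrix(body | fins, nrow = S))
}

# fish frame -> world (pixel) coordinates for an M x 2 point matrix
to_world <- function(pts, geom) {
  sc <- exp(geom$logscale); th <- geom$theta
  x <- pts[, 1] * sc; y <- pts[, 2] * sc
  cbind(cos(th) * x - sin(th) * y + geom$cx + geom$dx,
        sin(th) * x + cos(th) * y + geom$cy + geom$dy)
}

dilate_mask <- function(m, r = 2L) {
  out <- m
  for (dx in -r:r) for (dy in -r:r) {
    if (dx * dx + dy * dy > r * r) next
    sr <- (1 + max(0, dy)):(nrow(m) + min(0, dy))
    sc <- (1 + max(0, dx)):(ncol(m) + min(0, dx))
    out[sr, sc] <- out[sr, sc] | m[sr - dy, sc - dx]
  }
  out
}

artifact_geometry <- function(kind, S, rng_positions = NULL) {
  xs <- rep(0:(S - 1), each = S); ys <- rep(0:(S - 1), times = S)
  if (kind == "pin-blob") {
    m <- (xs - 0.80 * S)^2 + (ys - 0.30 * S)^2 <= (0.04 * S)^2
    matrix(m, nrow = S)
  } else if (kind == "dirt-specks") {
    m <- rep(FALSE, S * S)
    for (i in seq_len(nrow(rng_positions))) {
      m <- m | ((xs - rng_positions[i, 1])^2 +
                  (ys - rng_positions[i, 2])^2 <= (0.025 * S)^2)
    }
    matrix(m, nrow = S)
  } else ms_stop("unknown artifact kind", "morphsal_config_error")
}

#' Generate a synthetic labeled dataset
#'
#' Renders one fish-like silhouette per specimen with class-dependent shape
#' deformations, places the 14 landmarks on the corresponding parametric
#' outline points, injects class-correlated technical artifacts, adds
#' Gaussian pixel noise and quantizes to 8-bit grayscale.  Ground-truth
#' effect and artifact masks are recorded per effect region / artifact.
#'
#' @param spec A [synth_spec()] object.
#' @return An object of class `synth_dataset` with elements `images` (list of
#'   matrices in [0, 1]), `landmarks` (list of 14 x 2 matrices, pixel
#'   coordinates, 0-based), `labels` (integer vector, 0-based class ids),
#'   `truth_effect_mask`, `truth_artifact_mask` (named lists of logical
#'   matrices) and `spec`.
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "synth_spec"))
    ms_stop("spec must be a synth_spec object", "morphsal_config_error")
  S <- spec$image_side
  C <- length(spec$n_per_class)
  N <- sum(spec$n_per_class)
  set.seed(spec$seed)

  # dataset-level draws first (fixed artifact geometry)
  dirt_pos <- matrix(runif(16, 0.05 * S, 0.95 * S), ncol = 2)

  # per-class deformation amplitudes per region entry
  class_geom <- lapply(0:(C - 1), function(cl) {
    g <- base_geometry(S)
    for (ef in spec$effect_regions) {
      idx <- match(cl, ef$classes)
      if (!is.na(idx)) g <- apply_effect(g, ef$region, ef$amplitude[idx])
    }
    g
  })

  # ground-truth effect masks: reference render without vs with the region's
  # maximum amplitude, dilated by 2 px
  ref <- render_fish(base_geometry(S), S)
  truth_effect <- list()
  for (ef in spec$effect_regions) {
    amp <- max(abs(ef$amplitude))
    g <- apply_effect(base_geometry(S), ef$region, amp)
    alt <- render_fish(g, S)
    truth_effect[[ef$region]] <- dilate_mask(ref$img != alt$img, 2L)
  }
  truth_artifact <- list()
  for (af in spec$artifact_spec) {
    truth_artifact[[af$kind]] <- switch(
      af$kind,
      "background-gradient" = !dilate_mask(ref$fish, 2L),
      artifact_geometry(af$kind, S, dirt_pos))
  }

  labels <- rep(0:(C - 1), times = spec$n_per_class)
  j <- spec$jitter_sd
  images <- vector("list", N)
  landmarks <- vector("list", N)
  for (n in seq_len(N)) {
    cl <- labels[n]
    g <- class_geom[[cl + 1]]
    if (j > 0) {
      g$hump <- g$hump + rnorm(1, 0, j)
      g$b_belly <- max(0.05 * S, g$b_belly + rnorm(1, 0, 0.7 * j))
      g$a_snout <- max(0.10 * S, g$a_snout + rnorm(1, 0, 0.7 * j))
      g$tail_shift <- g$tail_shift + rnorm(1, 0, 0.7 * j)
      g$b_top <- max(0.05 * S, g$b_top + rnorm(1, 0, 0.5 * j))
      g$h_dorsal <- max(0.02 * S, g$h_dorsal + rnorm(1, 0, 0.5 * j))
      g$dx <- rnorm(1, 0, 1.5 * j); g$dy <- rnorm(1, 0, 1.5 * j)
      g$logscale <- rnorm(1, 0, 0.015 * j)
      g$theta <- rnorm(1, 0, 0.025 * j)
    }
    rf <- render_fish(g, S)
    img <- rf$img
    for (af in spec$artifact_spec) {
      p <- if (length(af$prob) == 1) af$prob else af$prob[cl + 1]
      present <- runif(1) < p
      if (!present) next
      if (af$kind == "background-gradient") {
        grad <- matrix(rep((0:(S - 1)) / (S - 1), each = S), nrow = S)
        img[!rf$fish] <- img[!rf$fish] + af$intensity * grad[!rf$fish]
      } else {
        am <- truth_artifact[[af$kind]]
        img[am] <- img[am] + af$intensity
      }
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(S * S, 0, spec$noise_sd), nrow = S)
    img <- pmin(pmax(img, 0), 1)
    images[[n]] <- round(img * 255) / 255
    lm <- to_world(fish_landmarks(g), g)
    if (j > 0) lm <- lm + matrix(rnorm(28, 0, 0.4 * j), ncol = 2)
    lm[, 1] <- pmin(S - 1, pmax(0, lm[, 1]))
    lm[, 2] <- pmin(S - 1, pmax(0, lm[, 2]))
    rownames(lm) <- landmark_acronyms()
    colnames(lm) <- c("x", "y")
    landmarks[[n]] <- lm
  }
  structure(list(images = images, landmarks = landmarks,
                 labels = as.integer(labels),
                 truth_effect_mask = truth_effect,
                 truth_artifact_mask = truth_artifact,
                 spec = spec),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("synth_dataset: %d specimens, %d classes, %dx%d px, %d landmarks\n",
              length(x$images), length(x$spec$n_per_class),
              x$spec$image_side, x$spec$image_side, x$spec$n_landmarks))
  cat(sprintf("  effects: %s | artifacts: %s\n",
              paste(names(x$truth_effect_mask), collapse = ", "),
              if (length(x$truth_artifact_mask))
                paste(names(x$truth_artifact_mask), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Saliency map container
#'
#' @param values Matrix of nonnegative, finite importance marks.
#' @param source_tag Free-text provenance tag.
#' @return Object of class `saliency_map`.
#' @export
saliency_map <- function(values, source_tag = "") {
  values <- as.matrix(values)
  if (!all(is.finite(values)) || any(values < 0))
    ms_stop("saliency values must be finite and nonnegative",
            "morphsal_input_error")
  structure(list(values = values, source_tag = source_tag),
            class = "saliency_map")
}

sal_values <- function(map) {
  if (inherits(map, "saliency_map")) map$values else as.matrix(map)
}

#' Generate a saliency-map fixture
#'
#' Builds test fixtures for the saliency significance test: under the null a
#' homogeneous marked point process (i.i.d. exponential(1) marks at every
#' pixel); under the alternative the same plus a sparse Gaussian bump of
#' large marks.
#'
#' @param side Grid side length in pixels (>= 16).
#' @param kind `"null"` or `"cluster"`.
#' @param cluster_center `(x, y)` center of the bump, 0-based pixel coords.
#' @param cluster_radius Bump radius (Gaussian sd) in pixels.
#' @param amplitude Peak mark value added at the bump center.
#' @param seed Integer seed.
#' @return A [saliency_map()].
#' @export
generate_saliency_fixture <- function(side, kind = c("null", "cluster"),
                                      cluster_center = c(side / 2, side / 2),
                                      cluster_radius = 3, amplitude = 10,
                                      seed = 1L) {
  kind <- match.arg(kind)
  if (side < 16) ms_stop("side must be at least 16", "morphsal_config_error")
  set.seed(seed)
  vals <- matrix(stats::rexp(side * side), nrow = side)
  if (kind == "cluster") {
    if (any(cluster_center < 0) || any(cluster_center > side - 1))
      ms_stop("cluster center outside grid", "morphsal_config_error")
    xs <- rep(0:(side - 1), each = side); ys <- rep(0:(side - 1), times = side)
    bump <- amplitude * exp(-((xs - cluster_center[1])^2 +
                                (ys - cluster_center[2])^2) /
                              (2 * cluster_radius^2))
    vals <- vals + matrix(bump, nrow = side)
  }
  saliency_map(vals, source_tag = paste0("fixture-", kind))
}

#' Write a synthetic dataset to a directory
#'
#' Images and masks are written as 8-bit grayscale PNG, landmarks and labels
#' as a CSV table (`id,label,x1,y1,...,x14,y14`), and the generating spec as
#' a flat key-value config file.  The written form round-trips bit-exactly
#' through [read_dataset()].
#'
#' @param ds A `synth_dataset`.
#' @param directory Output directory (created if missing).
#' @return Invisibly, the manifest file path.
#' @export
write_dataset <- function(ds, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(directory, "images"), showWarnings = FALSE)
  dir.create(file.path(directory, "masks"), showWarnings = FALSE)
  N <- length(ds$images)
  ids <- sprintf("spec%04d", seq_len(N))
  for (n in seq_len(N))
    png::writePNG(ds$images[[n]],
                  file.path(directory, "images", paste0(ids[n], ".png")))
  for (nm in names(ds$truth_effect_mask))
    png::writePNG(ds$truth_effect_mask[[nm]] * 1,
                  file.path(directory, "masks", paste0("effect_", nm, ".png")))
  for (nm in names(ds$truth_artifact_mask))
    png::writePNG(ds$truth_artifact_mask[[nm]] * 1,
                  file.path(directory, "masks", paste0("artifact_", nm, ".png")))
  lm_tab <- data.frame(id = ids, label = ds$labels)
  coords <- t(vapply(ds$landmarks, function(l) as.vector(t(l)), numeric(28)))
  colnames(coords) <- paste0(rep(c("x", "y"), 14), rep(1:14, each = 2))
  utils::write.csv(cbind(lm_tab, coords),
                   file.path(directory, "landmarks.csv"), row.names = FALSE)
  sp <- ds$spec
  eff <- vapply(sp$effect_regions, function(e)
    paste(e$region, paste(e$classes, collapse = ","),
          paste(e$amplitude, collapse = ","), sep = ";"), "")
  art <- vapply(sp$artifact_spec, function(a)
    paste(a$kind, paste(a$prob, collapse = ","), a$intensity, sep = ";"), "")
  cfg <- c(paste0("n_per_class=", paste(sp$n_per_class, collapse = ",")),
           paste0("image_side=", sp$image_side),
           paste0("noise_sd=", format(sp$noise_sd, digits = 17)),
           paste0("jitter_sd=", format(sp$jitter_sd, digits = 17)),
           paste0("seed=", sp$seed),
           if (length(eff)) paste0("effect=", eff),
           if (length(art)) paste0("artifact=", art))
  writeLines(cfg, file.path(directory, "spec.cfg"))
  manifest <- file.path(directory, "manifest.txt")
  writeLines(c("morphsal-dataset-v1", paste0("n=", N)), manifest)
  invisible(manifest)
}

#' Read a synthetic dataset from a directory
#'
#' @param directory Directory previously written by [write_dataset()].
#' @return A `synth_dataset`.
#' @export
read_dataset <- function(directory) {
  manifest <- file.path(directory, "manifest.txt")
  if (!file.exists(manifest))
    ms_stop(sprintf("no manifest in '%s'", directory), "morphsal_io_error")
  cfg <- readLines(file.path(directory, "spec.cfg"))
  getv <- function(key) {
    v <- sub(paste0("^", key, "="), "",
             grep(paste0("^", key, "="), cfg, value = TRUE))
    v[nzchar(v)]
  }
  num <- function(s) as.numeric(strsplit(s, ",")[[1]])
  eff <- lapply(getv("effect"), function(s) {
    p <- strsplit(s, ";")[[1]]
    effect_region(p[1], num(p[2]), num(p[3]))
  })
  art <- lapply(getv("artifact"), function(s) {
    p <- strsplit(s, ";")[[1]]
    artifact(p[1], num(p[2]), as.numeric(p[3]))
  })
  sp <- synth_spec(n_per_class = num(getv("n_per_class")),
                   image_side = as.integer(getv("image_side")),
                   effect_regions = eff, artifact_spec = art,
                   noise_sd = as.numeric(getv("noise_sd")),
                   jitter_sd = as.numeric(getv("jitter_sd")),
                   seed = as.integer(getv("seed")))
  tab <- utils::read.csv(file.path(directory, "landmarks.csv"),
                         stringsAsFactors = FALSE)
  ncoord <- ncol(tab) - 2L
  if (ncoord != 28L)
    ms_stop(sprintf("landmark table has %d coordinate columns, expected 28 (first id: %s)",
                    ncoord, tab$id[1]), "morphsal_io_error")
  N <- nrow(tab)
  images <- vector("list", N); landmarks <- vector("list", N)
  for (n in seq_len(N)) {
    f <- file.path(directory, "images", paste0(tab$id[n], ".png"))
    if (!file.exists(f))
      ms_stop(sprintf("missing image for specimen '%s'", tab$id[n]),
              "morphsal_io_error")
    images[[n]] <- png::readPNG(f)
    lm <- matrix(as.numeric(tab[n, -(1:2)]), ncol = 2, byrow = TRUE)
    rownames(lm) <- landmark_acronyms(); colnames(lm) <- c("x", "y")
    landmarks[[n]] <- lm
  }
  readmask <- function(f) png::readPNG(f) > 0.5
  effm <- list(); artm <- list()
  for (f in list.files(file.path(directory, "masks"),
                       pattern = "^effect_.*\\.png$", full.names = TRUE))
    effm[[sub("^effect_(.*)\\.png$", "\\1", basename(f))]] <- readmask(f)
  for (f in list.files(file.path(directory, "masks"),
                       pattern = "^artifact_.*\\.png$", full.names = TRUE))
    artm[[sub("^artifact_(.*)\\.png$", "\\1", basename(f))]] <- readmask(f)
  structure(list(images = images, landmarks = landmarks,
                 labels = as.integer(tab$label),
                 truth_effect_mask = effm, truth_artifact_mask = artm,
                 spec = sp),
            class = "synth_dataset")
}

#' Read landmark configurations from a TPS file
#'
#' Supports the minimal TPS dialect used by common morphometrics software:
#' `LM=<m>` blocks of `x y` coordinate lines, optionally followed by
#' `ID=<id>` lines.
#'
#' @param path Path to a TPS file.
#' @return A list of M x 2 landmark matrices, named by specimen id.
#' @export
read_tps <- function(path) {
  if (!file.exists(path))
    ms_stop(sprintf("TPS file '%s' not found", path), "morphsal_io_error")
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- list(); i <- 1; k <- 0
  while (i <= length(lines)) {
    if (!grepl("^LM=", lines[i], ignore.case = TRUE))
      ms_stop(sprintf("malformed TPS file at line %d: expected LM=", i),
              "morphsal_io_error")
    m <- as.integer(sub("^LM=", "", lines[i], ignore.case = TRUE))
    coords <- do.call(rbind, lapply(lines[(i + 1):(i + m)], function(s)
      as.numeric(strsplit(s, "[ \t]+")[[1]][1:2])))
    i <- i + m + 1; k <- k + 1
    id <- paste0("tps", k)
    if (i <= length(lines) && grepl("^ID=", lines[i], ignore.case = TRUE)) {
      id <- sub("^ID=", "", lines[i], ignore.case = TRUE)
      i <- i + 1
    }
    colnames(coords) <- c("x", "y")
    out[[id]] <- coords
  }
  out
}
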