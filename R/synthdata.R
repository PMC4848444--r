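# Seeded synthetic fundus-image generator: a bright retina disc with
# vessel tree, optic disc and macula; AREDS-category-dependent lesions
# (hard drusen, soft drusen, hemorrhages / geographic atrophy) and
# quality artifacts (blur, shadow, haze, arc).  Visual realism is
# secondary to carrying class signal in the texture and colour
# statistics that the feature families measure.

#' Specification of a synthetic dataset
#'
#' Default cell counts follow the category-by-quality distribution of a
#' 279-image telemedicine screening population: good quality
#' (50, 43, 24, 22) and poor quality (29, 36, 41, 34) for categories
#' 1..4.
#'
#' @param n_per_cell 2 x 4 matrix of counts (rows good/poor, columns
#'   categories 1..4).
#' @param image_side image side in pixels (default 192).
#' @param seed master seed; each image derives its own seed from it.
#' @param hard_drusen,soft_drusen,hemorrhage,atrophy lesion parameter
#'   lists (counts are Poisson means plus a minimum; radii/areas in
#'   pixels).
#' @param artifacts quality-artifact parameter list; `pool` restricts
#'   which artifact types poor images may receive (default all four:
#'   blur, shadow, haze, arc).
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_per_cell = matrix(c(50, 43, 24, 22,
                                             29, 36, 41, 34),
                                           2, 4, byrow = TRUE,
                                           dimnames = list(
                                             c("good", "poor"), 1:4)),
                       image_side = 192, seed = 1,
                       hard_drusen = list(n_min = 5, n_mean = 12,
                                          r_min = 1.2, r_max = 3),
                       soft_drusen = list(n_min = 4, n_mean = 7,
                                          r_min = 4.5, r_max = 10),
                       hemorrhage = list(n_min = 2, n_mean = 3,
                                         r_min = 6, r_max = 14),
                       atrophy = list(prob = 0.5, r_frac_min = 0.22,
                                      r_frac_max = 0.35),
                       artifacts = list(blur_max = 1 / 3, shadow_max = 0.6,
                                        haze_min = 0.25, haze_max = 0.6,
                                        arc_prob = 0.4,
                                        pool = c("blur", "shadow", "haze",
                                                 "arc"))) {
  if (any(n_per_cell < 0) || any(n_per_cell != round(n_per_cell)))
    stop("n_per_cell must hold non-negative integer counts")
  if (!all(dim(n_per_cell) == c(2, 4)))
    stop("n_per_cell must be 2 x 4 (quality x category)")
  dimnames(n_per_cell) <- list(c("good", "poor"), 1:4)
  if (image_side < 96) stop("image_side must be at least 96")
  if (is.null(artifacts$pool))
    artifacts$pool <- c("blur", "shadow", "haze", "arc")
  if (!all(artifacts$pool %in% c("blur", "shadow", "haze", "arc")) ||
      length(artifacts$pool) < 1)
    stop("artifact pool must be a non-empty subset of blur/shadow/haze/arc")
  pars <- c(unlist(hard_drusen), unlist(soft_drusen), unlist(hemorrhage),
            unlist(atrophy), unlist(artifacts[names(artifacts) != "pool"]))
  if (any(!is.finite(pars))) stop("lesion/artifact parameters must be finite")
  if (max(soft_drusen$r_max, hard_drusen$r_max, hemorrhage$r_max) >=
      0.46 * image_side)
    stop("lesion radii must be smaller than the retina radius")
  structure(list(n_per_cell = n_per_cell, image_side = image_side,
                 seed = seed, hard_drusen = hard_drusen,
                 soft_drusen = soft_drusen, hemorrhage = hemorrhage,
                 atrophy = atrophy, artifacts = artifacts),
            class = "synth_spec")
}

# Stamp an additive radial blob onto channel arrays (in place via
# returned array).  profile_pow 2 = diffuse Gaussian, 4 = sharp-edged.
.stamp <- function(px, row, col, radius, dRGB, alpha = 1, profile_pow = 2,
                   extent = 2.2) {
  n <- dim(px)[1]; m <- dim(px)[2]
  w <- ceiling(radius * extent)
  rs <- max(1, row - w):min(n, row + w)
  cs <- max(1, col - w):min(m, col + w)
  d2 <- outer((rs - row)^2, (cs - col)^2, "+")
  prof <- alpha * exp(-(sqrt(d2) / radius)^profile_pow)
  for (ch in 1:3)
    px[rs, cs, ch] <- px[rs, cs, ch] + dRGB[ch] * prof
  px
}

# Recursive branching vessel tree drawn into a weight mask.
.vessel_mask <- function(side, center, radius, origin) {
  mask <- matrix(0, side, side)
  draw_branch <- function(pos, heading, width, mask) {
    steps <- 0
    while (width >= 0.8 && steps < 400) {
      steps <- steps + 1
      heading <- heading + stats::rnorm(1, 0, 0.14)
      pos <- pos + 2.2 * c(-sin(heading), cos(heading))
      if (sqrt(sum((pos - center)^2)) > 0.96 * radius) break
      w <- max(1, round(width / 2))
      rs <- max(1, round(pos[1]) - w):min(side, round(pos[1]) + w)
      cs <- max(1, round(pos[2]) - w):min(side, round(pos[2]) + w)
      mask[rs, cs] <- pmax(mask[rs, cs], 1)
      if (stats::runif(1) < 0.035 && width > 1.2) {
        mask <- draw_branch(pos, heading + sample(c(-1, 1), 1) *
                              stats::runif(1, 0.4, 0.9),
                            width * 0.72, mask)
        width <- width * 0.9
      }
      width <- width * 0.995
    }
    mask
  }
  n_trunk <- sample(4:6, 1)
  for (t in seq_len(n_trunk)) {
    heading <- stats::runif(1, 0, 2 * pi)
    mask <- draw_branch(origin, heading, stats::runif(1, 2.6, 3.4), mask)
  }
  mask
}

#' Generate one synthetic fundus image
#'
#' @param spec a [synth_spec()].
#' @param category AREDS category 1..4.
#' @param quality `"good"` or `"poor"`.
#' @param id image id string.
#' @param seed seed for this image (all randomness flows from it).
#' @return a `fundus_image` with an extra `lesions` element (data.frame
#'   of ground-truth lesion primitives: type, row, col, radius).
#' @export
generate_fundus <- function(spec, category, quality, id, seed) {
  set.seed(seed)
  side <- spec$image_side
  ctr <- side / 2 + stats::runif(2, -2, 2)
  radius <- 0.46 * side - stats::runif(1, 0, 3)
  d2 <- outer((seq_len(side) - ctr[1])^2, (seq_len(side) - ctr[2])^2, "+")
  inside <- d2 <= radius^2
  dist <- sqrt(d2)

  px <- array(0, c(side, side, 3))
  # inter-subject fundus pigmentation: per-eye palette jitter plus a
  # global melanin factor, so colour varies across eyes as it does
  # across patients and cameras
  melanin <- stats::runif(1, 0.75, 1.15)
  base <- melanin * c(205 + stats::rnorm(1, 0, 18),
                      120 + stats::rnorm(1, 0, 14),
                      50 + stats::rnorm(1, 0, 10))
  base <- clip_range(base, 20, 250)
  vign <- 1 - 0.25 * (dist / radius)^2
  # smooth illumination gradient (random direction) + granular texture
  ang <- stats::runif(1, 0, 2 * pi)
  gradmap <- outer(seq_len(side) - ctr[1], rep(1, side)) * (-sin(ang)) +
    outer(rep(1, side), seq_len(side) - ctr[2]) * cos(ang)
  gradmap <- stats::runif(1, 10, 30) * gradmap / side
  tex <- gauss_blur(matrix(stats::rnorm(side^2, 0, 8), side), 1.6) +
    matrix(stats::rnorm(side^2, 0, 3), side)
  for (ch in 1:3)
    px[, , ch] <- (base[ch] * vign + gradmap + tex * c(0.7, 1, 0.5)[ch]) *
      inside

  # optic disc (bright, nasal side) and macula (darker, at centre)
  od_side <- sample(c(-1, 1), 1)
  od <- c(ctr[1] + stats::rnorm(1, 0, 4), ctr[2] + od_side * 0.62 * radius)
  px <- .stamp(px, round(od[1]), round(od[2]), 0.13 * radius,
               c(60, 95, 100), profile_pow = 4)
  px <- .stamp(px, round(ctr[1]), round(ctr[2]), 0.25 * radius,
               c(-25, -30, -8), profile_pow = 2)

  # vessel tree
  vm <- gauss_blur(.vessel_mask(side, ctr, radius, od), 0.7)
  vm <- pmin(vm, 1)
  vcol <- melanin * c(140, 45, 30) + stats::rnorm(3, 0, 6)
  for (ch in 1:3)
    px[, , ch] <- px[, , ch] * (1 - 0.85 * vm) + vcol[ch] * 0.85 * vm * inside

  # category-dependent lesions near the macula
  lesions <- data.frame(type = character(0), row = numeric(0),
                        col = numeric(0), radius = numeric(0))
  lesion_at <- function(rmax_frac = 0.5) {
    a <- stats::runif(1, 0, 2 * pi)
    r <- sqrt(stats::runif(1)) * rmax_frac * radius
    round(c(ctr[1] + r * cos(a), ctr[2] + r * sin(a)))
  }
  add_lesion <- function(type, pos, radius)
    rbind(lesions, data.frame(type = type, row = pos[1], col = pos[2],
                              radius = radius))
  if (category == 2) {
    n <- spec$hard_drusen$n_min + stats::rpois(1, spec$hard_drusen$n_mean)
    for (i in seq_len(n)) {
      p <- lesion_at(0.45)
      r <- stats::runif(1, spec$hard_drusen$r_min, spec$hard_drusen$r_max)
      px <- .stamp(px, p[1], p[2], r, c(40, 60, 8), profile_pow = 4)
      lesions <- add_lesion("hard_drusen", p, r)
    }
  } else if (category == 3) {
    n <- spec$soft_drusen$n_min + stats::rpois(1, spec$soft_drusen$n_mean)
    for (i in seq_len(n)) {
      p <- lesion_at(0.5)
      r <- stats::runif(1, spec$soft_drusen$r_min, spec$soft_drusen$r_max)
      px <- .stamp(px, p[1], p[2], r, c(34, 52, 6), profile_pow = 2)
      lesions <- add_lesion("soft_drusen", p, r)
    }
  } else if (category == 4) {
    if (stats::runif(1) < spec$atrophy$prob) {
      p <- lesion_at(0.2)
      r <- stats::runif(1, spec$atrophy$r_frac_min,
                        spec$atrophy$r_frac_max) * radius
      px <- .stamp(px, p[1], p[2], r, c(55, 95, 120), profile_pow = 3)
      lesions <- add_lesion("atrophy", p, r)
    } else {
      n <- spec$hemorrhage$n_min + stats::rpois(1, spec$hemorrhage$n_mean)
      for (i in seq_len(n)) {
        p <- lesion_at(0.5)
        r <- stats::runif(1, spec$hemorrhage$r_min, spec$hemorrhage$r_max)
        # irregular: union of three offset dark blobs
        for (j in 1:3) {
          off <- round(stats::runif(2, -0.5, 0.5) * r)
          px <- .stamp(px, p[1] + off[1], p[2] + off[2], 0.7 * r,
                       c(-90, -70, -18), profile_pow = 3)
        }
        lesions <- add_lesion("hemorrhage", p, r)
      }
    }
    n <- stats::rpois(1, 3)  # advanced eyes usually also carry drusen
    for (i in seq_len(n)) {
      p <- lesion_at(0.5)
      r <- stats::runif(1, spec$soft_drusen$r_min, spec$soft_drusen$r_max)
      px <- .stamp(px, p[1], p[2], r, c(34, 52, 6), profile_pow = 2)
      lesions <- add_lesion("soft_drusen", p, r)
    }
  }

  # dark background noise outside the retina
  bgn <- matrix(stats::runif(side^2, 2, 10), side)
  for (ch in 1:3) px[, , ch] <- px[, , ch] * inside + bgn * !inside
  px <- clip_range(px, 0, 255)

  if (quality == "poor") {
    arts <- spec$artifacts
    pool <- arts$pool
    chosen <- sample(pool, sample(seq_len(min(3, length(pool))), 1))
    for (a in chosen) {
      s <- switch(a,
        blur = stats::runif(1, 0.1, arts$blur_max),
        shadow = stats::runif(1, 0.3, arts$shadow_max),
        haze = stats::runif(1, arts$haze_min, arts$haze_max),
        arc = if (stats::runif(1) < arts$arc_prob / 0.4) {
          stats::runif(1, 0.4, 1)
        } else 0)
      if (s > 0) px <- degrade(px, a, s, seed = derive_seed(seed, match(a, pool)))
    }
  }

  img <- fundus_image(round(px), ctr, radius, label = category,
                      quality = quality, id = id)
  img$lesions <- lesions
  img
}

#' Apply a quality-degrading artifact to an image
#'
#' Artifacts emulate telemedicine acquisition problems: `blur`
#' (Gaussian, sigma = 3 * strength px), `shadow` (one-sided
#' multiplicative darkening), `haze` (additive veil mixing toward a
#' bright flat field; RMS contrast at strength 1 drops below half) and
#' `arc` (bright arc-shaped flash reflection).  Strength 0 returns the
#' input unchanged; blur and haze reduce RMS contrast monotonically.
#'
#' @param pixels H x W x 3 array (0..255) or `fundus_image`.
#' @param artifact one of `"blur"`, `"shadow"`, `"haze"`, `"arc"`.
#' @param strength in \[0, 1\].
#' @param seed seed for artifact geometry (direction / arc position).
#' @return degraded pixels (same form as the input).
#' @export
degrade <- function(pixels, artifact, strength, seed = 1) {
  was_img <- inherits(pixels, "fundus_image")
  img <- if (was_img) pixels else NULL
  px <- if (was_img) pixels$pixels else pixels
  if (!artifact %in% c("blur", "shadow", "haze", "arc"))
    stop("unknown artifact: ", artifact)
  stopifnot(strength >= 0, strength <= 1)
  if (strength > 0) {
    side <- dim(px)[1:2]
    set.seed(seed)
    px <- switch(artifact,
      blur = gauss_blur(px, 3 * strength),
      haze = (1 - 0.7 * strength) * px + 0.7 * strength * 200,
      shadow = {
        ang <- stats::runif(1, 0, 2 * pi)
        ramp <- outer(seq_len(side[1]) / side[1] - 0.5, rep(1, side[2])) *
          (-sin(ang)) +
          outer(rep(1, side[1]), seq_len(side[2]) / side[2] - 0.5) * cos(ang)
        fac <- 1 - 0.7 * strength * clip_range(ramp + 0.5, 0, 1)
        px * as.vector(fac)
      },
      arc = {
        ctr <- side / 2
        rr <- stats::runif(1, 0.55, 0.85) * min(side) / 2
        a0 <- stats::runif(1, 0, 2 * pi)
        d <- sqrt(outer((seq_len(side[1]) - ctr[1])^2,
                        (seq_len(side[2]) - ctr[2])^2, "+"))
        theta <- atan2(outer(seq_len(side[1]) - ctr[1], rep(1, side[2])),
                       outer(rep(1, side[1]), seq_len(side[2]) - ctr[2]))
        band <- exp(-((d - rr) / (0.03 * min(side)))^2) *
          (cos(theta - a0) > 0.3)
        for (ch in 1:3) px[, , ch] <- px[, , ch] + 90 * strength * band
        px
      })
    px <- clip_range(px, 0, 255)
  }
  if (was_img) { img$pixels <- px; img } else px
}

#' Generate a full synthetic dataset
#'
#' Images are generated cell by cell (quality x category, in the order
#' good/poor and categories 1..4); each image derives its own seed from
#' the spec seed and its index, so the dataset (and any single image) is
#' reproducible bit for bit.
#'
#' @param spec a [synth_spec()].
#' @param dir optional output directory; if given, PNGs, a
#'   `manifest.csv` (columns id, path, label, quality) and a
#'   ground-truth `lesions.json` are written there.
#' @return a list with `images` (list of `fundus_image`), `manifest`
#'   (data.frame) and `lesions` (named list of data.frames).
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  images <- list()
  rows <- list()
  idx <- 0L
  for (q in c("good", "poor")) {
    for (cat in 1:4) {
      for (i in seq_len(spec$n_per_cell[q, cat])) {
        idx <- idx + 1L
        id <- sprintf("synth_%03d", idx)
        img <- generate_fundus(spec, cat, q, id,
                               seed = derive_seed(spec$seed, idx))
        images[[idx]] <- img
        rows[[idx]] <- data.frame(id = id,
                                  path = paste0(id, ".png"),
                                  label = cat, quality = q)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  lesions <- lapply(images, `[[`, "lesions")
  names(lesions) <- manifest$id
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (img in images)
      png::writePNG(img$pixels / 255, file.path(dir, paste0(img$id, ".png")))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lesions, file.path(dir, "lesions.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  list(images = images, manifest = manifest, lesions = lesions)
}
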