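# Wrapped-normal machinery. Masses over arcs of [0,1) are computed by a
# truncated image sum over 2K+1 images of the line normal; K = 7 keeps the
# truncation error far below 1e-12 for any sd arising in practice.

.wnImages <- 7L

# P(position in [a, b)) for a wrapped N(mu, sd) on [0,1); 0 <= a < b <= 1.
.wnMass <- function(a, b, mu, sd) {
  if (sd == 0) {
    pos <- mu %% 1
    return(as.numeric(pos >= a & pos < b))
  }
  k <- seq(-.wnImages, .wnImages)
  sum(pnorm(b + k, mean = mu %% 1, sd = sd) -
      pnorm(a + k, mean = mu %% 1, sd = sd))
}

# Density of the wrapped normal at points theta in [0,1).
.wnDensity <- function(theta, mu, sd) {
  k <- seq(-.wnImages, .wnImages)
  rowSums(vapply(k, function(ki) dnorm(theta + ki, mean = mu %% 1, sd = sd),
                 numeric(length(theta))))
}

# Mass over an arc that may wrap past 1 (start > end means wrapping).
.wnArcMass <- function(arc, mu, sd) {
  if (arc[1] <= arc[2]) .wnMass(arc[1], arc[2], mu, sd)
  else .wnMass(arc[1], 1, mu, sd) + .wnMass(0, arc[2], mu, sd)
}

#' Wrapped-normal position parameters at given times
#'
#' @param model a \linkS4class{SynchronyModel}.
#' @param times hours after release.
#' @return data.frame time, mean (cycle fraction, unwrapped), sd.
#' @export
positionDistribution <- function(model, times) {
  data.frame(time = times,
             mean = model@releasePosition + times / model@cycleLength,
             sd = sqrt(model@sigma0^2 + (model@kappa * times)^2))
}

#' Simulate FACS phase fractions of a synchronized population
#'
#' Computes the wrapped-normal mass over each phase arc at every time
#' point, then produces per-replicate rows that differ only by a small
#' seeded measurement jitter (renormalized to sum to one).
#'
#' @param model a \linkS4class{SynchronyModel}.
#' @param design a \linkS4class{TimeCourseDesign}.
#' @param seed integer master seed.
#' @param jitterSd standard deviation of the replicate jitter on the
#'   fraction scale (default 0.01).
#' @return A \linkS4class{FacsFractions}.
#' @examples
#' f <- simulateSynchrony(SynchronyModel(), TimeCourseDesign(), seed = 1)
#' fractions(f)["Epi1_3h", "S"]  # ~0.87: most cells in first S phase
#' @export
simulateSynchrony <- function(model, design, seed, jitterSd = 0.01) {
  .assert(model@sigma0 >= 0 && model@kappa >= 0,
          "dispersion parameters must be nonnegative")
  pos <- positionDistribution(model, design@timePoints)
  base <- t(vapply(seq_len(nrow(pos)), function(i) {
    vapply(c("G1", "S", "G2M"), function(ph) {
      .wnArcMass(model@phaseIntervals[[ph]], pos$mean[i], pos$sd[i])
    }, numeric(1))
  }, numeric(3)))
  colnames(base) <- c("G1", "S", "G2M")
  grid <- sampleGrid(design)
  frac <- .withSeed(.subSeed(seed, "synchrony"), {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      ti <- match(grid$time[i], design@timePoints)
      f <- base[ti, ] + rnorm(3, sd = jitterSd)
      f <- pmax(f, 1e-9)
      f / sum(f)
    })
    do.call(rbind, rows)
  })
  rownames(frac) <- grid$sample
  colnames(frac) <- c("G1", "S", "G2M")
  new("FacsFractions", fractions = frac, positions = pos)
}

# Map a peak-phase position to one of the five phase labels used for
# marker-based assignment. Sub-arc boundaries sit inside the simulator's
# three FACS arcs: the G1/S label straddles the release boundary at 0.
.defaultPhaseBoundaries <- list(
  "G1/S" = c(0.95, 0.07),  # wraps through 0
  "S"    = c(0.07, 0.35),
  "G2"   = c(0.35, 0.50),
  "G2/M" = c(0.50, 0.60),
  "M/G1" = c(0.60, 0.95))

#' Map cycle positions to the five phase labels
#'
#' Deterministic mapping from a peak-phase position on [0,1) to the labels
#' G1/S, S, G2, G2/M, M/G1, using configurable sub-arcs of the simulator's
#' G1/S/G2M arcs. Used to turn ground-truth peak phases into the label
#' space of marker-based assignment.
#'
#' @param psi numeric vector of cycle fractions in [0,1).
#' @param boundaries named list of \code{c(start, end)} arcs; an arc with
#'   start > end wraps through 0. Default splits the cycle at
#'   0.07/0.35/0.50/0.60/0.95.
#' @return character vector of phase labels.
#' @export
phaseLabelOf <- function(psi, boundaries = .defaultPhaseBoundaries) {
  vapply(psi %% 1, function(p) {
    for (lab in names(boundaries)) {
      a <- boundaries[[lab]]
      inArc <- if (a[1] <= a[2]) (p >= a[1] && p < a[2])
               else (p >= a[1] || p < a[2])
      if (inArc) return(lab)
    }
    NA_character_
  }, character(1))
}

#' The five cell-cycle phase labels in canonical order
#' @return character vector.
#' @export
phaseLevels <- function() c("G1/S", "S", "G2", "G2/M", "M/G1")
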