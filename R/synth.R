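# Synthetic planted-solution instances.
#
# The generator emulates the statistical shape of a fragment-docking run
# without any external docking tool: a linear chain compound (an ideal
# all-anti alkane of K ethane units) is decomposed into K rigid fragments;
# the native fragment poses are planted as one placement per fragment, and
# decoys are scattered around them by random rigid transforms.  Planted
# placements draw favorable binding-free-energy scores, decoys draw from a
# broader, less favorable distribution — mirroring real fragment docking,
# where good and mediocre placements coexist as candidates.

.BOND_CC <- 1.526
.BOND_CH <- 1.09

# ideal all-anti n-alkane with explicit hydrogens (zig-zag in the xz plane)
.idealAlkane <- function(nC) {
  stopifnot(nC >= 2)
  half <- (180 - 112) / 2 * pi / 180
  dx <- .BOND_CC * cos(half)
  dz <- .BOND_CC * sin(half)
  cxyz <- cbind((seq_len(nC) - 1) * dx, 0, (seq_len(nC) %% 2) * dz)

  elem <- rep("C", nC)
  xyz <- cxyz
  a1 <- seq_len(nC - 1); a2 <- a1 + 1L
  ord <- rep(1L, nC - 1)

  addH <- function(pos) {
    elem <<- c(elem, "H")
    xyz <<- rbind(xyz, pos)
    length(elem)
  }
  unit <- function(v) v / sqrt(sum(v^2))
  for (i in seq_len(nC)) {
    nb <- c(if (i > 1) i - 1L, if (i < nC) i + 1L)
    c0 <- cxyz[i, ]
    if (length(nb) == 2L) {
      n1 <- unit(cxyz[nb[1], ] - c0); n2 <- unit(cxyz[nb[2], ] - c0)
      bis <- unit(-(n1 + n2))
      perp <- unit(c(n1[2] * n2[3] - n1[3] * n2[2],
                     n1[3] * n2[1] - n1[1] * n2[3],
                     n1[1] * n2[2] - n1[2] * n2[1]))
      phi <- 107.8 / 2 * pi / 180
      for (s in c(1, -1)) {
        hIdx <- addH(c0 + .BOND_CH * (bis * cos(phi) + s * perp * sin(phi)))
        a1 <- c(a1, i); a2 <- c(a2, hIdx); ord <- c(ord, 1L)
      }
    } else {
      a <- unit(cxyz[nb[1], ] - c0)
      e1 <- unit(if (abs(a[1]) < 0.9) c(1, 0, 0) - a * a[1] else
                   c(0, 1, 0) - a * a[2])
      e2 <- c(a[2] * e1[3] - a[3] * e1[2],
              a[3] * e1[1] - a[1] * e1[3],
              a[1] * e1[2] - a[2] * e1[1])
      ct <- cos(109.47 * pi / 180); st <- sin(109.47 * pi / 180)
      for (k in 0:2) {
        d <- ct * a + st * (cos(2 * pi * k / 3) * e1 + sin(2 * pi * k / 3) * e2)
        hIdx <- addH(c0 + .BOND_CH * d)
        a1 <- c(a1, i); a2 <- c(a2, hIdx); ord <- c(ord, 1L)
      }
    }
  }
  cmp <- new("Compound",
             atoms = data.frame(elem = elem,
                                charge = rep(0L, length(elem)),
                                stringsAsFactors = FALSE),
             bonds = data.frame(a1 = a1, a2 = a2, order = ord,
                                ring = rep(FALSE, length(a1))),
             coords = unname(xyz),
             id = sprintf("synthetic_alkane_C%d", nC))
  validObject(cmp)
  cmp
}

# uniform random rotation matrix (quaternion method)
.randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Default configuration for the synthetic instance generator
#'
#' The defaults emulate the conditions of a small redocking run: four
#' fragments (the size of the reference compound's decomposition), five
#' placements per fragment, planted scores drawn near -6 kcal/mol (the
#' best band observed in fragment docking) and decoy scores from a
#' broader band near -2 kcal/mol, decoys displaced by ~3 Angstrom rigid
#' perturbations, geometric pair-term mode.
#'
#' @param K fragment count (chain length K ethane units).
#' @param m placements per fragment (1 planted + m-1 decoys).
#' @param displacement decoy rigid-transform translation scale (Angstrom).
#' @param plantedMean,plantedSd planted score distribution (kcal/mol).
#' @param decoyMean,decoySd decoy score distribution (kcal/mol).
#' @param clashFraction fraction of decoys relocated on top of another
#'   fragment's planted pose (guaranteed steric clash).
#' @param mode pair-term mode, "geometric" or "energy".
#' @param thE energy tolerance for energy mode (kcal/mol).
#' @param clashDistance,bondWindow geometric-mode thresholds (Angstrom).
#' @param seed optional integer seed.
#' @return a named list.
#' @export
generatorConfig <- function(K = 4L, m = 5L, displacement = 3.0,
                            plantedMean = -6, plantedSd = 0.5,
                            decoyMean = -2, decoySd = 1.0,
                            clashFraction = 0,
                            mode = c("geometric", "energy"),
                            thE = 500, clashDistance = 2.0,
                            bondWindow = c(1.2, 2.0), seed = NULL) {
  mode <- match.arg(mode)
  if (K < 1 || m < 1) stop("K and m must be at least 1")
  list(K = as.integer(K), m = as.integer(m), displacement = displacement,
       plantedMean = plantedMean, plantedSd = plantedSd,
       decoyMean = decoyMean, decoySd = decoySd,
       clashFraction = clashFraction, mode = mode, thE = thE,
       clashDistance = clashDistance, bondWindow = bondWindow, seed = seed)
}

# negative-truncated normal score
.negScore <- function(mean, sd) {
  for (it in 1:100) {
    v <- stats::rnorm(1, mean, sd)
    if (v < 0) return(v)
  }
  -1e-3
}

#' Generate a synthetic docking instance with a planted solution
#'
#' Builds a chain compound of K rigid ethane fragments, plants the native
#' fragment poses as one placement per fragment (attachment distances equal
#' to the chain bond length, inside the bond window), scatters `m - 1`
#' decoys per fragment by random rigid transforms, assigns scores, computes
#' pair terms in the configured mode, and verifies that the planted vector
#' is feasible: valid (H4 = 0), clash-free, and connected along every
#' chain bond.
#'
#' @param config list from [generatorConfig()].
#' @return a [SyntheticInstance-class].
#' @examples
#' inst <- generateInstance(generatorConfig(K = 3, m = 2, seed = 1))
#' inst
#' @export
generateInstance <- function(config = generatorConfig()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  K <- config$K; m <- config$m
  cmp <- .idealAlkane(2L * K)
  fr <- decompose(cmp)
  if (length(fr@fragments) != K)
    stop("internal error: chain did not decompose into K fragments")

  centroids <- lapply(fr@fragments, function(f)
    .heavyCentroid(f, f@compound@coords))

  entries <- list()
  plantedIdx <- integer(0)
  for (k in seq_len(K)) {
    frag <- fr@fragments[[k]]
    native <- frag@compound@coords
    entries[[length(entries) + 1L]] <-
      list(fragment = k, score = .negScore(config$plantedMean,
                                           config$plantedSd),
           coords = native)
    plantedIdx <- c(plantedIdx, length(entries))
    nd <- m - 1L
    for (d in seq_len(nd)) {
      ok <- FALSE
      for (try in 1:100) {
        R <- .randomRotation()
        ctr <- centroids[[k]]
        moved <- sweep(native, 2, ctr) %*% t(R)
        target <- if (K > 1 && stats::runif(1) < config$clashFraction) {
          other <- sample(setdiff(seq_len(K), k), 1)
          centroids[[other]] + stats::rnorm(3, 0, 0.3)
        } else {
          ctr + stats::rnorm(3, 0, config$displacement)
        }
        moved <- sweep(moved, 2, target, "+")
        if (.poseRMSD(frag, moved, native) > 0.1) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place a decoy distinct from the planted pose")
      entries[[length(entries) + 1L]] <-
        list(fragment = k, score = .negScore(config$decoyMean,
                                             config$decoySd),
             coords = moved)
    }
  }

  ps <- placementSet(entries, fr)
  # placementSet preserves insertion order (fragment-major, planted first)
  planted <- integer(nrow(ps@table))
  planted[plantedIdx] <- 1L

  terms <- pairTerms(ps, mode = config$mode, thE = config$thE,
                     clashDistance = config$clashDistance,
                     bondWindow = config$bondWindow)

  # feasibility guarantees of the planted selection
  qubo <- buildQUBO(ps, terms)
  bd <- evalHamiltonian(qubo, planted)
  if (bd$H4 != 0) stop("planted selection is not valid (H4 != 0)")
  if (bd$H2 != 0) stop("planted selection contains a clash")
  if (bd$H3 != -(K - 1))
    stop("planted selection is not fully connected along the chain")

  obj <- new("SyntheticInstance", compound = cmp, fragmentation = fr,
             placements = ps, terms = terms, planted = planted,
             config = config)
  validObject(obj)
  obj
}

#' Score-band summary of an instance (per-fragment score ranges)
#'
#' The synthetic counterpart of a fragment-docking result table: per
#' fragment, the number of candidate placements and the minimum (best) and
#' maximum (worst) binding-free-energy scores.
#'
#' @param instance a [SyntheticInstance-class] or [PlacementSet-class].
#' @return data.frame with columns `fragment`, `smiles`, `n`, `minScore`,
#'   `maxScore`.
#' @export
scorebandReport <- function(instance) {
  ps <- if (is(instance, "SyntheticInstance")) instance@placements else
    instance
  tb <- ps@table
  frs <- ps@fragmentation@fragments
  if (!nrow(tb))
    return(data.frame(fragment = integer(0), smiles = character(0),
                      n = integer(0), minScore = numeric(0),
                      maxScore = numeric(0)))
  out <- do.call(rbind, lapply(sort(unique(tb$fragment)), function(k) {
    s <- tb$score[tb$fragment == k]
    data.frame(fragment = k, smiles = frs[[k]]@smiles,
               n = length(s), minScore = min(s), maxScore = max(s))
  }))
  rownames(out) <- NULL
  out
}
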