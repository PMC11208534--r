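#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats approx cor dist dnorm fft hclust cutree median quantile
#'   runif rnorm sd var lm coef prcomp predict
#' @importFrom utils head read.csv write.csv modifyList
NULL

.TRANSFORM_TAGS <- c("raw", "sqrt", "zscored", "whitened")

#' Firing-rate matrix (neurons x time)
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a neurons x
#' time matrix of firing rates in the \code{"rates"} assay. The column data
#' carry the sample times (\code{t}, seconds), the speed-filter mask
#' (\code{keep}) and, when available, running speed. Metadata record the sample
#' step \code{dt} and the provenance of the values (\code{"raw"},
#' \code{"sqrt"}, \code{"zscored"} or \code{"whitened"}).
#'
#' @export
setClass("RateMatrix", contains = "SummarizedExperiment")

setValidity("RateMatrix", function(object) {
  md <- S4Vectors::metadata(object)
  if (is.null(md$dt) || !is.numeric(md$dt) || md$dt <= 0)
    return("metadata 'dt' must be a positive number")
  if (is.null(md$transform) || !md$transform %in% .TRANSFORM_TAGS)
    return(sprintf("metadata 'transform' must be one of %s",
                   paste(.TRANSFORM_TAGS, collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("t", "keep") %in% colnames(cd)))
    return("colData must contain 't' and 'keep'")
  if (!is.logical(cd$keep)) return("'keep' mask must be logical")
  v <- SummarizedExperiment::assay(object, "rates")
  if (md$transform %in% c("raw", "sqrt") && any(v < 0, na.rm = TRUE))
    return("raw/sqrt rates must be nonnegative")
  TRUE
})

#' Construct a RateMatrix
#'
#' @param values numeric matrix, neurons x time.
#' @param dt sample step in seconds.
#' @param transform provenance tag of the values.
#' @param t sample times (seconds); defaults to \code{(0:(T-1)) * dt}.
#' @param keep logical speed-filter mask over time bins.
#' @param speed optional running speed per time bin (cm/s).
#' @return A \linkS4class{RateMatrix}.
#' @export
RateMatrix <- function(values, dt, transform = "raw", t = NULL, keep = NULL,
                       speed = NULL) {
  values <- as.matrix(values)
  if (is.null(t)) t <- (seq_len(ncol(values)) - 1) * dt
  if (is.null(keep)) keep <- rep(TRUE, ncol(values))
  cd <- S4Vectors::DataFrame(t = t, keep = keep)
  if (!is.null(speed)) cd$speed <- speed
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rates = values), colData = cd,
    metadata = list(dt = dt, transform = transform))
  new("RateMatrix", se)
}

#' Spike trains of a recorded population
#'
#' Sorted event times (seconds) per neuron, with the recording span.
#'
#' @slot times list of numeric vectors, one per neuron, sorted ascending.
#' @slot span numeric(2), recording start and end (seconds).
#' @slot ids character neuron identifiers.
#' @export
setClass("SpikeTrainSet",
         representation(times = "list", span = "numeric", ids = "character"))

setValidity("SpikeTrainSet", function(object) {
  if (length(object@span) != 2 || diff(object@span) < 0)
    return("span must be c(start, end) with end >= start")
  for (tr in object@times) {
    if (length(tr) && (is.unsorted(tr) || min(tr) < object@span[1] ||
                       max(tr) > object@span[2]))
      return("spike times must be sorted and lie within the recording span")
  }
  if (length(object@ids) != length(object@times))
    return("one id per neuron required")
  TRUE
})

#' @param times list of per-neuron spike time vectors (seconds).
#' @param span recording span \code{c(start, end)}; defaults to the data range.
#' @param ids neuron identifiers.
#' @rdname SpikeTrainSet-class
#' @export
SpikeTrainSet <- function(times, span = NULL, ids = NULL) {
  times <- lapply(times, function(x) sort(as.numeric(x)))
  if (is.null(span)) {
    all_t <- unlist(times)
    span <- if (length(all_t)) c(0, max(all_t)) else c(0, 0)
  }
  if (is.null(ids)) ids <- as.character(seq_along(times))
  new("SpikeTrainSet", times = times, span = as.numeric(span),
      ids = as.character(ids))
}

#' Behavioral trajectory sample
#'
#' Tracking of the animal (or simulated walker): time, position, running speed
#' and heading. Speed and heading are derived from position differences when
#' not supplied.
#'
#' @slot t seconds, strictly increasing.
#' @slot x,y position in cm.
#' @slot speed cm/s.
#' @slot heading movement direction, radians in [0, 2*pi).
#' @export
setClass("TrajectorySample",
         representation(t = "numeric", x = "numeric", y = "numeric",
                        speed = "numeric", heading = "numeric"))

setValidity("TrajectorySample", function(object) {
  n <- length(object@t)
  if (any(lengths(list(object@x, object@y, object@speed, object@heading)) != n))
    return("all fields must have equal length")
  if (n > 1 && any(diff(object@t) <= 0)) return("t must be strictly increasing")
  if (any(object@speed < 0)) return("speed must be nonnegative")
  TRUE
})

#' @param t,x,y time (s) and position (cm).
#' @param speed,heading optional kinematics; derived from displacements if NULL.
#' @rdname TrajectorySample-class
#' @export
TrajectorySample <- function(t, x, y, speed = NULL, heading = NULL) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (is.null(speed) || is.null(heading)) {
    dx <- c(diff(x), 0); dy <- c(diff(y), 0); dt <- c(diff(t), NA)
    dt[length(dt)] <- if (length(dt) > 1) dt[length(dt) - 1] else 1
    sp <- sqrt(dx^2 + dy^2) / dt
    hd <- atan2(dy, dx) %% (2 * pi)
    if (length(sp) > 1) {
      sp[length(sp)] <- sp[length(sp) - 1]
      hd[length(hd)] <- hd[length(hd) - 1]
    }
    if (is.null(speed)) speed <- sp
    if (is.null(heading)) heading <- hd
  }
  new("TrajectorySample", t = t, x = x, y = y, speed = as.numeric(speed),
      heading = as.numeric(heading) %% (2 * pi))
}

#' Continuous attractor network configuration
#'
#' Parameters of the three grid-module simulators. The inhibitory-sheet model
#' uses \code{drive}, \code{velocityGain}, \code{dirOffset}, \code{connRadius},
#' \code{inhibW} and \code{relax}; the twisted/square torus models use
#' \code{gridGain} plus the divisive-normalization constants in \code{extra}
#' (\code{intensity}, \code{sigma}, \code{tshift}, \code{tau}).
#'
#' @export
setClass("CANConfig",
         representation(model = "character", nRows = "integer",
                        nCols = "integer", drive = "numeric",
                        velocityGain = "numeric", dirOffset = "numeric",
                        connRadius = "numeric", inhibW = "numeric",
                        relax = "numeric", gridGain = "numeric",
                        dt = "numeric", stabilizationSteps = "integer",
                        rateFloor = "numeric", seed = "integer",
                        extra = "list"))

setValidity("CANConfig", function(object) {
  if (!object@model %in% c("inhibitory_sheet", "twisted_torus", "square_torus"))
    return("unknown model")
  if (object@relax <= 0) return("relax (rho) must be positive")
  if (object@dt <= 0) return("dt must be positive")
  if (object@rateFloor < 0) return("rateFloor must be nonnegative")
  TRUE
})

#' @param model one of \code{"inhibitory_sheet"}, \code{"twisted_torus"},
#'   \code{"square_torus"}.
#' @param nRows,nCols sheet dimensions; defaults are 56 x 44 (sheet), 20 x 20
#'   (twisted torus) and 10 x 10 (square torus).
#' @param drive excitatory drive J (sheet model).
#' @param velocityGain velocity gain gamma (sheet model).
#' @param dirOffset preferred-direction offset l in sheet units.
#' @param connRadius connectivity radius R in sheet units.
#' @param inhibW inhibitory weight W0.
#' @param relax relaxation constant rho.
#' @param gridGain velocity gain of the torus models.
#' @param dt integration step (s).
#' @param stabilizationSteps settling iterations at zero velocity.
#' @param rateFloor rates below this are zeroed on output (sheet model).
#' @param seed RNG seed for the random initial state.
#' @param extra divisive-normalization constants for the torus models.
#' @rdname CANConfig-class
#' @export
canConfig <- function(model = c("twisted_torus", "inhibitory_sheet",
                                "square_torus"),
                      nRows = NULL, nCols = NULL, drive = 1,
                      velocityGain = 0.15, dirOffset = 2, connRadius = 20,
                      inhibW = -0.01, relax = 10, gridGain = 0.06,
                      dt = NULL, stabilizationSteps = NULL, rateFloor = 1e-4,
                      seed = 1L,
                      extra = list(intensity = 0.3, sigma = 0.24,
                                   tshift = 0.05, tau = 0.8)) {
  model <- match.arg(model)
  if (is.null(nRows))
    nRows <- switch(model, inhibitory_sheet = 56L, twisted_torus = 20L,
                    square_torus = 10L)
  if (is.null(nCols))
    nCols <- switch(model, inhibitory_sheet = 44L, twisted_torus = 20L,
                    square_torus = 10L)
  if (is.null(dt))
    dt <- switch(model, inhibitory_sheet = 0.002, twisted_torus = 0.01,
                 square_torus = 0.02)
  if (is.null(stabilizationSteps))
    stabilizationSteps <- switch(model, inhibitory_sheet = 2000L, 500L)
  new("CANConfig", model = model, nRows = as.integer(nRows),
      nCols = as.integer(nCols), drive = drive, velocityGain = velocityGain,
      dirOffset = dirOffset, connRadius = connRadius, inhibW = inhibW,
      relax = relax, gridGain = gridGain, dt = dt,
      stabilizationSteps = as.integer(stabilizationSteps),
      rateFloor = rateFloor, seed = as.integer(seed), extra = extra)
}

#' Simulator output
#'
#' @slot rates a \linkS4class{RateMatrix} (neurons x time).
#' @slot unitPhases per-unit preferred phase on the network sheet (N x 2).
#' @slot trajectory the driving \linkS4class{TrajectorySample}.
#' @slot bumpPhase tracked activity-bump phase per kept frame (T x 2 angles),
#'   the simulator's ground truth for decoding tests.
#' @slot config the \linkS4class{CANConfig} used.
#' @export
setClass("SimOutput",
         representation(rates = "RateMatrix", unitPhases = "matrix",
                        trajectory = "TrajectorySample", bumpPhase = "matrix",
                        config = "CANConfig"))

#' Point cloud with provenance
#'
#' @slot points m x d coordinate matrix.
#' @slot index integer original (time) indices of the rows.
#' @export
setClass("PointCloud",
         representation(points = "matrix", index = "integer"))

setValidity("PointCloud", function(object) {
  if (!all(is.finite(object@points))) return("points must be finite")
  if (length(object@index) != nrow(object@points))
    return("one index per point required")
  if (anyDuplicated(object@index)) return("indices must be unique")
  TRUE
})

#' @param points coordinate matrix (rows are points).
#' @param index original indices; defaults to row numbers.
#' @rdname PointCloud-class
#' @export
PointCloud <- function(points, index = NULL) {
  points <- as.matrix(points)
  if (is.null(index)) index <- seq_len(nrow(points))
  new("PointCloud", points = points, index = as.integer(index))
}

#' Fuzzy neighborhood memberships of a point cloud
#'
#' @slot sigma per-point scale parameter solving the membership-sum equation.
#' @slot neighbors kappa-nearest-neighbor index matrix (m x kappa).
#' @slot mu symmetric pairwise membership matrix in [0, 1].
#' @slot kappa neighborhood size.
#' @export
setClass("FuzzyMembership",
         representation(sigma = "numeric", neighbors = "matrix",
                        mu = "matrix", kappa = "integer"))

#' Persistence barcode
#'
#' @slot bars data.frame with columns dim, birth, death, lifetime.
#' @slot cocycles list of representative 1-cocycles (integer matrices with
#'   columns vertex_i, vertex_j, coeff), one per H1 bar; names give the bar row.
#' @slot metric distance used ("cosine" or "euclidean").
#' @slot modulus coefficient field prime.
#' @slot threshold filtration truncation value (enclosing radius by default).
#' @slot shuffleThresholds per-dimension 99th-percentile lifetime thresholds
#'   from the time-roll shuffle null (NA until \code{shuffleNull} is run).
#' @export
setClass("Barcode",
         representation(bars = "data.frame", cocycles = "list",
                        metric = "character", modulus = "integer",
                        threshold = "numeric", shuffleThresholds = "numeric"))

setValidity("Barcode", function(object) {
  b <- object@bars
  if (!all(c("dim", "birth", "death", "lifetime") %in% colnames(b)))
    return("bars must have dim, birth, death, lifetime")
  fin <- is.finite(b$death)
  if (any(b$birth[fin] > b$death[fin])) return("birth must not exceed death")
  th <- object@shuffleThresholds
  if (length(th) && any(!is.na(th) & th < 0))
    return("shuffle thresholds must be nonnegative")
  TRUE
})

#' Circle-valued coordinate on landmarks
#'
#' @slot angle per-landmark angle in [0, 2*pi).
#' @slot barId row of the source bar in the barcode.
#' @slot tau filtration scale at which the cocycle was smoothed.
#' @export
setClass("CircularCoordinate",
         representation(angle = "numeric", barId = "integer", tau = "numeric"))

#' Decoded toroidal coordinates over time
#'
#' @slot angles T x n matrix of angles in [0, 2*pi).
#' @slot t sample times (seconds).
#' @slot valid logical mask; FALSE where the decoding was undefined.
#' @slot distributions per-dimension list of neuron x bin circular activity
#'   distributions used for extrapolation.
#' @slot nBins histogram resolution of the distributions.
#' @export
setClass("ToroidalCoordinates",
         representation(angles = "matrix", t = "numeric", valid = "logical",
                        distributions = "list", nBins = "integer"))

setValidity("ToroidalCoordinates", function(object) {
  a <- object@angles[object@valid, , drop = FALSE]
  if (length(a) && (any(!is.finite(a)) || any(a < 0) || any(a >= 2 * pi + 1e-9)))
    return("valid angles must be finite and in [0, 2*pi)")
  if (length(object@valid) != nrow(object@angles))
    return("one validity flag per time point required")
  TRUE
})

#' Ensemble partition of a population
#'
#' @slot labels integer cluster label per neuron; 0 marks neurons in clusters
#'   smaller than \code{minSize} (disregarded).
#' @slot distance symmetric correlation-distance matrix between neurons.
#' @slot rho clustering cut height (correlation-distance units).
#' @slot minSize smallest retained ensemble.
#' @export
setClass("EnsemblePartition",
         representation(labels = "integer", distance = "matrix",
                        rho = "numeric", minSize = "integer"))

setValidity("EnsemblePartition", function(object) {
  D <- object@distance
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    return("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-8)) return("distance diagonal must be zero")
  if (length(object@labels) != nrow(D))
    return("one label per neuron required")
  tab <- table(object@labels[object@labels > 0])
  if (length(tab) && min(tab) < object@minSize)
    return("retained ensembles must have at least minSize members")
  TRUE
})

#' Toroidal change of coordinates
#'
#' An element of the discrete symmetry group of the (hexagonal) torus: an
#' integer unimodular matrix acting on the pair of angles, composed with
#' per-axis offsets, mapping one decoded torus onto another.
#'
#' @slot matrix 2 x 2 integer matrix with |det| = 1.
#' @slot offsets per-axis angular offsets (radians).
#' @export
setClass("TorusTransform",
         representation(matrix = "matrix", offsets = "numeric"))

setValidity("TorusTransform", function(object) {
  m <- object@matrix
  if (!all(dim(m) == c(2, 2))) return("matrix must be 2 x 2")
  if (abs(abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) - 1) > 1e-9)
    return("matrix must be unimodular")
  if (length(object@offsets) != 2) return("two offsets required")
  TRUE
})

#' Hexagonal/square torus classification of an ensemble
#'
#' @slot hexCorr best heat-model correlation per unit, hexagonal kernel
#'   (maximum over the two axis orientations).
#' @slot sqrCorr heat-model correlation per unit, square kernel.
#' @slot hexMedian,sqrMedian ensemble medians.
#' @slot label "hexagonal", "square" or "unclassified".
#' @export
setClass("TorusClassification",
         representation(hexCorr = "numeric", sqrCorr = "numeric",
                        hexMedian = "numeric", sqrMedian = "numeric",
                        label = "character"))

#' Preprocessing parameter profile
#'
#' Bundles the tunable constants of the pipeline: rate-smoothing kernel widths
#' and sample steps, PCA dimension, downsampling constants, clustering cut and
#' the speed filter. Defaults mirror a Neuropixels open-field profile.
#'
#' @slot sigmaSmooth Gaussian kernel width for the topology rates (s).
#' @slot sigmaCluster kernel width for the clustering rates (s).
#' @slot dtTopology,dtCluster sample steps (s).
#' @slot d number of whitened principal components.
#' @slot eps radial-downsampling radius.
#' @slot kappa fuzzy neighborhood size.
#' @slot m number of landmarks kept by fuzzy downsampling.
#' @slot rhoCluster agglomerative clustering cut (correlation distance).
#' @slot tauMax maximum cross-correlation lag (s).
#' @slot speedMin speed filter (cm/s).
#' @export
setClass("ParameterProfile",
         representation(sigmaSmooth = "numeric", sigmaCluster = "numeric",
                        dtTopology = "numeric", dtCluster = "numeric",
                        d = "integer", eps = "numeric", kappa = "integer",
                        m = "integer", rhoCluster = "numeric",
                        tauMax = "numeric", speedMin = "numeric"))

setValidity("ParameterProfile", function(object) {
  pos <- c(object@sigmaSmooth, object@sigmaCluster, object@dtTopology,
           object@dtCluster, object@d, object@eps, object@kappa, object@m,
           object@tauMax)
  if (any(pos <= 0)) return("profile constants must be positive")
  if (object@speedMin < 0) return("speedMin must be nonnegative")
  TRUE
})

#' @param sigmaSmooth,sigmaCluster,dtTopology,dtCluster,d,eps,kappa,m,rhoCluster,tauMax,speedMin
#'   see the class slots.
#' @rdname ParameterProfile-class
#' @export
parameterProfile <- function(sigmaSmooth = 0.06, sigmaCluster = 0.3,
                             dtTopology = 0.02, dtCluster = 0.1, d = 6L,
                             eps = 0.8, kappa = 1000L, m = 2200L,
                             rhoCluster = 0.4, tauMax = 3, speedMin = 5) {
  new("ParameterProfile", sigmaSmooth = sigmaSmooth,
      sigmaCluster = sigmaCluster, dtTopology = dtTopology,
      dtCluster = dtCluster, d = as.integer(d), eps = eps,
      kappa = as.integer(kappa), m = as.integer(m), rhoCluster = rhoCluster,
      tauMax = tauMax, speedMin = speedMin)
}
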