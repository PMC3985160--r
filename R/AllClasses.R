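#' @import methods
#' @importFrom stats predict runif rgamma sd var rmultinom
#' @importFrom utils head write.csv read.csv
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Per-dimension affine scaler onto [-1, 1]
#'
#' Stores the per-column minimum and maximum of a training feature matrix.
#' [applyScaler()] maps each column affinely so that the training range
#' [min, max] becomes [-1, 1]; constant columns map to 0.  Test data
#' transformed with training statistics may fall outside [-1, 1].
#'
#' @slot min numeric, per-column training minima.
#' @slot max numeric, per-column training maxima.
#' @seealso [fitScaler()], [applyScaler()]
#' @export
setClass("FeatureScaler",
  representation(min = "numeric", max = "numeric"),
  validity = function(object) {
    if (length(object@min) != length(object@max))
      return("min and max must have equal length")
    if (any(object@max < object@min))
      return("max must be >= min in every dimension")
    TRUE
  })

setClassUnion("FeatureScalerOrNULL", c("FeatureScaler", "NULL"))

#' Random hidden layer of a single-hidden-layer feedforward network
#'
#' Hidden-node parameters drawn once at random and never updated: a J x d
#' weight (or, for Gaussian nodes, centre) matrix and a length-J bias
#' (width) vector, together with the node kind and the seed that fully
#' determines them.
#'
#' @slot kind character, one of `"linear"`, `"sigmoid"`, `"gaussian"`.
#' @slot weights J x d numeric matrix of node weights / centres.
#' @slot bias numeric length J; biases, or widths (> 0) for Gaussian nodes.
#' @slot seed integer seed the layer was drawn from.
#' @seealso [initHiddenLayer()], [hiddenOutput()]
#' @export
setClass("HiddenLayer",
  representation(kind = "character", weights = "matrix", bias = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (!object@kind %in% c("linear", "sigmoid", "gaussian"))
      return("kind must be linear, sigmoid or gaussian")
    if (nrow(object@weights) < 1L) return("at least one hidden node required")
    if (length(object@bias) != nrow(object@weights))
      return("bias length must equal the number of hidden nodes")
    if (object@kind == "gaussian" && any(object@bias <= 0))
      return("gaussian widths must be strictly positive")
    TRUE
  })

#' Single-hidden-layer feedforward network trained by ELM
#'
#' A fitted SLFN classifier: the random [HiddenLayer-class], the J x C
#' output-weight matrix solved in closed form by the Moore-Penrose
#' pseudoinverse, the fixed class ordering, and (optionally) the
#' [FeatureScaler-class] the training features were normalised with.
#'
#' @slot hidden a [HiddenLayer-class].
#' @slot outputWeights J x C numeric matrix W with O = H W.
#' @slot classLevels character vector fixing the class index (sorted labels).
#' @slot scaler optional [FeatureScaler-class] (or NULL).
#' @seealso [trainELM()], [predict()][predict,SLFNModel-method]
#' @export
setClass("SLFNModel",
  representation(hidden = "HiddenLayer", outputWeights = "matrix",
                 classLevels = "character", scaler = "FeatureScalerOrNULL"),
  validity = function(object) {
    if (nrow(object@outputWeights) != nrow(object@hidden@weights))
      return("outputWeights must have one row per hidden node")
    if (ncol(object@outputWeights) != length(object@classLevels))
      return("outputWeights must have one column per class")
    if (length(object@classLevels) < 2L) return("at least two classes required")
    TRUE
  })

#' Optimally pruned ELM model
#'
#' An [SLFNModel-class] whose hidden nodes are the subset of an initial pool
#' of `Jmax` nodes selected by multiresponse sparse regression ranking
#' followed by PRESS leave-one-out minimisation.  Extra slots record the
#' full neuron ranking, the LOO error per candidate neuron count, and the
#' selected count.
#'
#' @slot ranking integer permutation of 1..Jmax, most relevant neuron first.
#' @slot looError numeric; PRESS leave-one-out error for neuron counts 1..Jmax.
#' @slot selectedK integer; the smallest argmin of `looError`.
#' @seealso [trainOPELM()], [pressCurve()]
#' @export
setClass("OPELMModel",
  contains = "SLFNModel",
  representation(ranking = "integer", looError = "numeric",
                 selectedK = "integer"),
  validity = function(object) {
    J <- length(object@ranking)
    if (!setequal(object@ranking, seq_len(J)))
      return("ranking must be a permutation of 1..Jmax")
    if (length(object@looError) != J)
      return("looError must have one value per candidate neuron count")
    k <- object@selectedK
    if (k < 1L || k > J) return("selectedK out of range")
    if (abs(object@looError[k] - min(object@looError)) > 1e-12)
      return("selectedK must attain the minimum LOO error")
    TRUE
  })

#' Majority-voting ensemble of independently trained SLFNs
#'
#' K base models sharing the same architecture and activation, trained
#' independently on the full training set with member seeds derived
#' deterministically from a single master seed.  Classification is by
#' majority vote over member predictions (V-ELM when the base learner is
#' ELM, VOP-ELM when it is OP-ELM).
#'
#' @slot baseKind character, `"elm"` or `"opelm"`.
#' @slot members list of K fitted [SLFNModel-class] / [OPELMModel-class].
#' @slot masterSeed integer master seed the member seeds derive from.
#' @slot classLevels character; shared class ordering of the members.
#' @seealso [trainEnsemble()], [voteTallies()]
#' @export
setClass("ELMEnsemble",
  representation(baseKind = "character", members = "list",
                 masterSeed = "integer", classLevels = "character"),
  validity = function(object) {
    if (!object@baseKind %in% c("elm", "opelm"))
      return("baseKind must be elm or opelm")
    if (length(object@members) < 1L) return("K must be >= 1")
    ok <- vapply(object@members, is, logical(1), class2 = "SLFNModel")
    if (!all(ok)) return("all members must be SLFNModel objects")
    same <- vapply(object@members,
                   function(m) identical(m@classLevels, object@classLevels),
                   logical(1))
    if (!all(same)) return("members must share the ensemble class levels")
    TRUE
  })

#' Class-specific residue composition profile
#'
#' Generating profile for one synthetic superfamily: a composition bias
#' over the 20 amino acids, an optional first-order transition bias, and a
#' sequence length range.
#'
#' @slot name profile (class) name.
#' @slot residueWeights named numeric length 20, positive, summing to 1.
#' @slot lengthRange integer length 2, min >= 2.
#' @slot transitionBias optional 20 x 20 positive matrix (row = current
#'   residue) multiplied into the composition to give first-order Markov
#'   transition probabilities; NULL for i.i.d. sampling.
#' @seealso [makeProfiles()], [generateDataset()]
#' @export
setClass("SuperfamilyProfile",
  representation(name = "character", residueWeights = "numeric",
                 lengthRange = "integer", transitionBias = "matrixOrNULL"),
  validity = function(object) {
    if (length(object@residueWeights) != 20L)
      return("residueWeights must have 20 entries")
    if (any(object@residueWeights <= 0)) return("residueWeights must be > 0")
    if (length(object@lengthRange) != 2L || object@lengthRange[1] < 2L ||
        object@lengthRange[2] < object@lengthRange[1])
      return("lengthRange must be (min, max) with min >= 2")
    if (!is.null(object@transitionBias) &&
        !all(dim(object@transitionBias) == c(20L, 20L)))
      return("transitionBias must be 20 x 20")
    TRUE
  })

#' Labelled protein sequence dataset
#'
#' Sequences (a Biostrings AAStringSet, names = record ids) with a parallel
#' factor of superfamily labels; synthetic datasets also carry their
#' generating profiles and seed.
#'
#' @slot sequences an `AAStringSet`; names are unique record ids.
#' @slot labels factor, one label per sequence.
#' @slot profiles list of [SuperfamilyProfile-class] (may be empty for
#'   datasets read from files).
#' @slot seed integer generation seed (NA for file-derived data).
#' @seealso [generateDataset()], [readProteinFasta()]
#' @export
setClass("ProteinDataset",
  representation(sequences = "AAStringSet", labels = "factor",
                 profiles = "list", seed = "integer"),
  validity = function(object) {
    if (length(object@sequences) != length(object@labels))
      return("sequences and labels must have equal length")
    if (length(object@sequences) &&
        anyDuplicated(names(object@sequences)))
      return("record ids must be unique")
    TRUE
  })

#' Repeated-trial experiment report
#'
#' Per-trial test classification rates from [runExperiment()], with their
#' mean and standard deviation (the paper-style Rate / Dev summary) and
#' informational wall times.
#'
#' @slot algorithm character, the algorithm evaluated.
#' @slot accuracy numeric, per-trial test accuracy in [0, 1].
#' @slot wallTime numeric, per-trial training time in seconds (informational).
#' @slot config list of the experiment configuration used.
#' @export
setClass("TrialReport",
  representation(algorithm = "character", accuracy = "numeric",
                 wallTime = "numeric", config = "list"),
  validity = function(object) {
    if (length(object@accuracy) < 1L) return("at least one trial required")
    if (any(object@accuracy < 0 | object@accuracy > 1))
      return("accuracy must lie in [0, 1]")
    TRUE
  })
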