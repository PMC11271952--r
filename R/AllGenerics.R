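#' Accessors for BOLD runs and trial-pattern sets
#'
#' @param object a \code{\linkS4class{BoldRun}} or
#'   \code{\linkS4class{TrialPatternSet}}
#' @return \code{boldData} and \code{patternData} return the voxel x
#'   timepoint / voxel x trial matrix; \code{framewiseDisplacement} the FD
#'   trace (mm); \code{motionParams} the timepoint x 6 motion matrix;
#'   \code{repetitionTime}, \code{roiLabel}, \code{runLabel},
#'   \code{taskLabel} the corresponding scalars; \code{patternInfo} the
#'   per-trial metadata data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("boldData", function(object) standardGeneric("boldData"))
#' @rdname accessors
#' @export
setMethod("boldData", "BoldRun", function(object)
    SummarizedExperiment::assay(object, "bold"))

#' @rdname accessors
#' @export
setGeneric("framewiseDisplacement",
           function(object) standardGeneric("framewiseDisplacement"))
#' @rdname accessors
#' @export
setMethod("framewiseDisplacement", "BoldRun", function(object)
    colData(object)$fd)

#' @rdname accessors
#' @export
setGeneric("motionParams", function(object) standardGeneric("motionParams"))
#' @rdname accessors
#' @export
setMethod("motionParams", "BoldRun", function(object) {
    cd <- colData(object)
    as.matrix(as.data.frame(cd[, paste0("motion", 1:6)]))
})

#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(object) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setMethod("repetitionTime", "BoldRun", function(object) metadata(object)$tr)

#' @rdname accessors
#' @export
setGeneric("roiLabel", function(object) standardGeneric("roiLabel"))
#' @rdname accessors
#' @export
setMethod("roiLabel", "BoldRun", function(object) metadata(object)$roi)
#' @rdname accessors
#' @export
setMethod("roiLabel", "TrialPatternSet", function(object) metadata(object)$roi)

#' @rdname accessors
#' @export
setGeneric("runLabel", function(object) standardGeneric("runLabel"))
#' @rdname accessors
#' @export
setMethod("runLabel", "BoldRun", function(object) metadata(object)$run)

#' @rdname accessors
#' @export
setGeneric("taskLabel", function(object) standardGeneric("taskLabel"))
#' @rdname accessors
#' @export
setMethod("taskLabel", "BoldRun", function(object) metadata(object)$task)

#' @rdname accessors
#' @export
setGeneric("patternData", function(object) standardGeneric("patternData"))
#' @rdname accessors
#' @export
setMethod("patternData", "TrialPatternSet", function(object)
    SummarizedExperiment::assay(object, "tstat"))

#' @rdname accessors
#' @export
setGeneric("patternInfo", function(object) standardGeneric("patternInfo"))
#' @rdname accessors
#' @export
setMethod("patternInfo", "TrialPatternSet", function(object)
    as.data.frame(colData(object)))

#' Design-matrix accessors
#'
#' @param object a \code{\linkS4class{DesignMatrix}}
#' @return \code{designMatrix} returns the timepoint x regressor matrix,
#'   \code{columnRoles} the named role vector, \code{frameTimes} the volume
#'   times in seconds.
#' @name design-accessors
NULL

#' @rdname design-accessors
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))
#' @rdname design-accessors
#' @export
setMethod("designMatrix", "DesignMatrix", function(object) object@matrix)

#' @rdname design-accessors
#' @export
setGeneric("columnRoles", function(object) standardGeneric("columnRoles"))
#' @rdname design-accessors
#' @export
setMethod("columnRoles", "DesignMatrix", function(object) object@role)

#' @rdname design-accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @rdname design-accessors
#' @export
setMethod("frameTimes", "DesignMatrix", function(object) object@frameTimes)
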