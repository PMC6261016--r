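#' Accessors for package classes
#'
#' \code{indicators} returns the patients x conditions matrix;
#' \code{patientIDs} and \code{conditionNames} its dimnames;
#' \code{mixingProportions}, \code{difficulties}, \code{discrimination},
#' \code{traitMeans}, \code{traitSDs} the corresponding model parameters;
#' \code{selectedItems} the items surviving Mokken selection; \code{bicOf}
#' the BIC of a fit.
#'
#' @param x an object of the corresponding class.
#' @return The slot contents (never access slots directly).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("indicators", function(x) standardGeneric("indicators"))
#' @rdname accessors
#' @export
setGeneric("patientIDs", function(x) standardGeneric("patientIDs"))
#' @rdname accessors
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))
#' @rdname accessors
#' @export
setGeneric("mixingProportions",
           function(x) standardGeneric("mixingProportions"))
#' @rdname accessors
#' @export
setGeneric("difficulties", function(x) standardGeneric("difficulties"))
#' @rdname accessors
#' @export
setGeneric("discrimination", function(x) standardGeneric("discrimination"))
#' @rdname accessors
#' @export
setGeneric("traitMeans", function(x) standardGeneric("traitMeans"))
#' @rdname accessors
#' @export
setGeneric("traitSDs", function(x) standardGeneric("traitSDs"))
#' @rdname accessors
#' @export
setGeneric("selectedItems", function(x) standardGeneric("selectedItems"))
#' @rdname accessors
#' @export
setGeneric("bicOf", function(x) standardGeneric("bicOf"))
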