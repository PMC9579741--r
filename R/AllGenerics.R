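#' @importFrom BiocGenerics counts
NULL

#' @rdname CompositionProfile-class
#' @param object,x a \code{CompositionProfile}.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname CompositionProfile-class
#' @export
setGeneric("readsSampled", function(x) standardGeneric("readsSampled"))

#' @rdname CompositionProfile-class
#' @export
setGeneric("readsTotal", function(x) standardGeneric("readsTotal"))

#' @rdname ReferenceDatabase-class
#' @export
setGeneric("libraryType", function(x) standardGeneric("libraryType"))

#' Feature matrix of a reference database
#'
#' Returns the S x (4L) matrix consumed by the embedding: one row per
#' sample, columns \code{pos1_A, pos1_C, pos1_G, pos1_T, ..., posL_T};
#' every four-column block sums to 100.
#'
#' @param x a [ReferenceDatabase].
#' @return numeric matrix with sample identifiers as row names; library-type
#'   labels are available via [libraryType()].
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Fit the 2-D reference map
#'
#' Runs UMAP on the composition feature matrix to produce the reference map:
#' a 2-D coordinate per reference sample plus the transform state used to
#' project new libraries onto the same manifold.
#'
#' @param x a [ReferenceDatabase] or a numeric S x (4L) feature matrix.
#' @param ... passed on; see the method for arguments.
#' @return a [ReferenceMap].
#' @export
setGeneric("fitReferenceMap", function(x, ...) standardGeneric("fitReferenceMap"))
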