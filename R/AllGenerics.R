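#' @name fl16s-accessors
#' @title Accessors for fl16s containers
#' @description Accessor generics for [CcsReadSet-class], [OtuSet-class] and
#'   [TaxDb-class] objects.
#' @param x An fl16s container object.
#' @param value Replacement value.
#' @param i Index for subsetting.
#' @param j,drop,... Ignored (present for generic signature compatibility).
NULL

#' @rdname fl16s-accessors
#' @export
setGeneric("readSequences", function(x) standardGeneric("readSequences"))
#' @rdname fl16s-accessors
#' @export
setGeneric("readIds", function(x) standardGeneric("readIds"))
#' @rdname fl16s-accessors
#' @export
setGeneric("readQualities", function(x) standardGeneric("readQualities"))
#' @rdname fl16s-accessors
#' @export
setGeneric("passCounts", function(x) standardGeneric("passCounts"))
#' @rdname fl16s-accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))
#' @rdname fl16s-accessors
#' @export
setGeneric("sampleLabels<-",
           function(x, value) standardGeneric("sampleLabels<-"))
#' @rdname fl16s-accessors
#' @export
setGeneric("expectedErrors", function(x) standardGeneric("expectedErrors"))
#' @rdname fl16s-accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname fl16s-accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))
#' @rdname fl16s-accessors
#' @export
setGeneric("otuTaxonomy", function(x) standardGeneric("otuTaxonomy"))
#' @rdname fl16s-accessors
#' @export
setGeneric("dbSequences", function(x) standardGeneric("dbSequences"))
#' @rdname fl16s-accessors
#' @export
setGeneric("dbLineage", function(x) standardGeneric("dbLineage"))

#' @rdname fl16s-accessors
#' @export
setMethod("readSequences", "CcsReadSet", function(x) x@sequences)
#' @rdname fl16s-accessors
#' @export
setMethod("readIds", "CcsReadSet", function(x) names(x@sequences))
#' @rdname fl16s-accessors
#' @export
setMethod("readQualities", "CcsReadSet", function(x) {
  q <- lapply(x@quality, function(s)
    if (nchar(s)) utf8ToInt(s) - 33L else integer(0))
  names(q) <- readIds(x)
  q
})
#' @rdname fl16s-accessors
#' @export
setMethod("passCounts", "CcsReadSet",
          function(x) setNames(x@passes, readIds(x)))
#' @rdname fl16s-accessors
#' @export
setMethod("sampleLabels", "CcsReadSet",
          function(x) setNames(x@sample, readIds(x)))
#' @rdname fl16s-accessors
#' @export
setMethod("sampleLabels<-", "CcsReadSet", function(x, value) {
  x@sample <- rep_len(as.character(value), length(x))
  validObject(x)
  x
})

#' @rdname fl16s-accessors
#' @export
setMethod("length", "CcsReadSet", function(x) length(x@sequences))

#' @rdname fl16s-accessors
#' @export
setMethod("[", "CcsReadSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, readIds(x))
  new("CcsReadSet",
      sequences = x@sequences[i],
      quality = x@quality[i],
      passes = x@passes[i],
      sample = x@sample[i])
})

setMethod("show", "CcsReadSet", function(object) {
  n <- length(object)
  cat(sprintf("CcsReadSet with %d read%s\n", n, if (n == 1) "" else "s"))
  if (n) {
    w <- Biostrings::width(object@sequences)
    cat(sprintf("  length: %d-%d (median %d)\n",
                min(w), max(w), as.integer(stats::median(w))))
    cat(sprintf("  with qualities: %d; with pass counts: %d; samples: %d\n",
                sum(nchar(object@quality) > 0), sum(!is.na(object@passes)),
                length(unique(stats::na.omit(object@sample)))))
  }
})

#' @rdname fl16s-accessors
#' @export
setMethod("centroids", "OtuSet", function(x) x@centroids)
#' @rdname fl16s-accessors
#' @export
setMethod("otuCounts", "OtuSet", function(x) x@counts)
#' @rdname fl16s-accessors
#' @export
setMethod("otuTaxonomy", "OtuSet", function(x) x@taxonomy)
#' @rdname fl16s-accessors
#' @export
setMethod("length", "OtuSet", function(x) length(x@centroids))

setMethod("show", "OtuSet", function(object) {
  cat(sprintf("OtuSet with %d OTUs (%d CHIM1 discards, %d CHIM2 removals)\n",
              length(object@centroids), nrow(object@chim1),
              length(object@chim2)))
  if (length(object@counts))
    cat(sprintf("  count table: %d OTUs x %d samples\n",
                nrow(object@counts), ncol(object@counts)))
})

#' @rdname fl16s-accessors
#' @export
setMethod("dbSequences", "TaxDb", function(x) x@sequences)
#' @rdname fl16s-accessors
#' @export
setMethod("dbLineage", "TaxDb", function(x) x@lineage)
#' @rdname fl16s-accessors
#' @export
setMethod("length", "TaxDb", function(x) length(x@sequences))

setMethod("show", "TaxDb", function(object) {
  cat(sprintf("TaxDb with %d entries, %d distinct species, %d families\n",
              length(object@sequences),
              length(unique(stats::na.omit(object@lineage$species))),
              length(unique(stats::na.omit(object@lineage$family)))))
})

setMethod("show", "GlobalAlignment", function(object) {
  cat(sprintf(
    "GlobalAlignment: identity %.4f (%d match, %d mismatch, %d internal gap)\n",
    object@identity, object@matches, object@mismatches,
    object@internal_gap_columns))
})

setMethod("show", "CommunitySpec", function(object) {
  cat(sprintf("CommunitySpec: %d species (%d reference copies)\n",
              nrow(object@lineage), length(object@references)))
})
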