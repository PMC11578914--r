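## Accessors and show methods.

#' Number of items
#' @param x a PopulationSpec, OrdinalDataset, or CfaModel.
#' @return integer.
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname nItems
#' @export
setMethod("nItems", "PopulationSpec", function(x) length(x@items))
#' @rdname nItems
#' @export
setMethod("nItems", "OrdinalDataset", function(x) ncol(x@items))
#' @rdname nItems
#' @export
setMethod("nItems", "CfaModel", function(x) length(x@items))

#' Number of response categories
#' @param x a PopulationSpec or OrdinalDataset.
#' @return integer.
#' @export
setGeneric("nCategories", function(x) standardGeneric("nCategories"))
#' @rdname nCategories
#' @export
setMethod("nCategories", "PopulationSpec", function(x) x@nCategories)
#' @rdname nCategories
#' @export
setMethod("nCategories", "OrdinalDataset", function(x) x@nCategories)

#' Group labels
#' @param x a PopulationSpec, OrdinalDataset or CfaFit.
#' @return character vector.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname groupLabels
#' @export
setMethod("groupLabels", "PopulationSpec", function(x) x@groupInfo$label)
#' @rdname groupLabels
#' @export
setMethod("groupLabels", "OrdinalDataset", function(x) unique(as.character(x@groups$label)))
#' @rdname groupLabels
#' @export
setMethod("groupLabels", "CfaFit", function(x) x@model@groups)

#' Item response matrix
#' @param x an OrdinalDataset.
#' @return integer matrix (n x K), NA = missing.
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))
#' @rdname responses
#' @export
setMethod("responses", "OrdinalDataset", function(x) x@items)

#' Group assignment data frame
#' @param x an OrdinalDataset.
#' @return data.frame with at least a \code{label} column.
#' @export
setGeneric("groupData", function(x) standardGeneric("groupData"))
#' @rdname groupData
#' @export
setMethod("groupData", "OrdinalDataset", function(x) x@groups)

#' Polychoric correlation matrix
#' @param x a PolychoricMoments object.
#' @return K x K matrix.
#' @export
setGeneric("polychoricCor", function(x) standardGeneric("polychoricCor"))
#' @rdname polychoricCor
#' @export
setMethod("polychoricCor", "PolychoricMoments", function(x) x@rho)

#' Threshold estimates
#' @param x a PolychoricMoments object.
#' @return list of per-item threshold vectors.
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
#' @rdname thresholds
#' @export
setMethod("thresholds", "PolychoricMoments", function(x) x@thresholds)

#' Fit indices of a fitted model
#' @param x a CfaFit.
#' @return named numeric vector (cfi, tli, rmsea, rmsea.lo, rmsea.hi, srmr).
#' @export
setGeneric("indices", function(x) standardGeneric("indices"))
#' @rdname indices
#' @export
setMethod("indices", "CfaFit", function(x) x@indices)

#' Parameter estimate table
#' @param x a CfaFit.
#' @return data.frame with one row per model parameter (type, item, cat,
#'   group, est, se).
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))
#' @rdname estimates
#' @export
setMethod("estimates", "CfaFit", function(x) x@estimates)

#' Achieved invariance level
#' @param x a LadderResult.
#' @return character scalar.
#' @export
setGeneric("achievedLevel", function(x) standardGeneric("achievedLevel"))
#' @rdname achievedLevel
#' @export
setMethod("achievedLevel", "LadderResult", function(x) x@level)

#' Step comparison table of an invariance ladder
#' @param x a LadderResult.
#' @return data.frame mirroring a measurement-invariance summary table
#'   (model, chisq, df, cfi, rmsea + CI, tli, srmr, delta indices, decision).
#' @export
setGeneric("comparisonTable", function(x) standardGeneric("comparisonTable"))
#' @rdname comparisonTable
#' @export
setMethod("comparisonTable", "LadderResult", function(x) x@comparisons)

setMethod("show", "PopulationSpec", function(object) {
  cat("PopulationSpec:", length(object@items), "items,",
      object@nCategories, "categories,", nrow(object@groupInfo), "groups\n")
  cat("  total N:", sum(object@groupInfo$n),
      " missingness:", object@missRate, paste0("(", object@missMode, ")\n"))
  if (nrow(object@residualPairs))
    cat("  correlated residual pairs:",
        paste(apply(object@residualPairs, 1, paste, collapse = "-"), collapse = ", "), "\n")
  if (nrow(object@injections))
    cat("  injections:", nrow(object@injections), "recorded\n")
})

setMethod("show", "OrdinalDataset", function(object) {
  cat("OrdinalDataset:", nrow(object@items), "x", ncol(object@items),
      " categories 1..", object@nCategories, "\n", sep = "")
  cat("  groups:", length(unique(object@groups$label)),
      " missing cells:", sum(is.na(object@items)), "\n")
})

setMethod("show", "PolychoricMoments", function(object) {
  cat("PolychoricMoments for group '", object@group, "' (n = ", object@n, ")\n", sep = "")
  cat("  items:", length(object@items),
      " correlations:", sum(upper.tri(object@rho)), "\n")
})

setMethod("show", "CfaModel", function(object) {
  cat("CfaModel (", object@level, "): ", length(object@items), " items, ",
      length(object@groups), " group(s), ",
      sum(object@template$free), " free parameters\n", sep = "")
})

setMethod("show", "CfaFit", function(object) {
  cat("CfaFit (", object@model@level, "): chisq = ",
      format(object@chisq, digits = 5), ", df = ", object@df, "\n", sep = "")
  ix <- object@indices
  cat(sprintf("  CFI = %.4f  TLI = %.4f  RMSEA = %.4f [%.4f, %.4f]  SRMR = %.4f\n",
              ix["cfi"], ix["tli"], ix["rmsea"], ix["rmsea.lo"], ix["rmsea.hi"],
              ix["srmr"]))
  if (!object@converged) cat("  WARNING: not converged\n")
})

setMethod("show", "LadderResult", function(object) {
  cat("Invariance ladder over '", object@grouping, "': achieved level '",
      object@level, "'\n", sep = "")
  print(object@comparisons, digits = 4)
})

setMethod("show", "DimensionalityReport", function(object) {
  cat("Parallel analysis (", object@corMethod, ", ", object@nSets,
      " sets, ", object@percentile, "th percentile)\n", sep = "")
  cat("  retained factors:", object@retained,
      " eigenvalue ratio:", format(object@ratio, digits = 4),
      " unidimensional:", object@unidimensional, "\n")
})
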