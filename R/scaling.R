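# Signed min-max scaling of load matrices.

#' Signed min-max scaling
#'
#' Scales each numeric column by its maximum absolute value, preserving
#' the sign, so values fall in [-1, 1]. The transform is idempotent.
#' All-zero columns are left unscaled with a warning. An alternative
#' interpretation (scale |x| linearly onto [0, 1] between min|x| and
#' max|x|, then reapply the sign) is available via \code{method}.
#'
#' @param x numeric matrix or data frame of load observations.
#' @param method \code{"maxabs"} (default) or \code{"absminmax"}.
#' @return Object of the same shape with scaled numeric columns.
#' @export
minmax_scale_signed <- function(x, method = c("maxabs", "absminmax")) {
  method <- match.arg(method)
  df <- is.data.frame(x)
  m <- if (df) x else as.data.frame(x)
  num <- vapply(m, is.numeric, logical(1))
  for (j in which(num)) {
    v <- m[[j]]
    amax <- max(abs(v), na.rm = TRUE)
    if (!is.finite(amax) || amax == 0) {
      warning("all-zero column left unscaled: ", names(m)[j])
      next
    }
    if (method == "maxabs") {
      m[[j]] <- v / amax
    } else {
      amin <- min(abs(v), na.rm = TRUE)
      if (amax == amin) {
        m[[j]] <- sign(v)
      } else {
        m[[j]] <- sign(v) * (abs(v) - amin) / (amax - amin)
      }
    }
  }
  if (df) m else as.matrix(m)
}

#' Build a per-observation load matrix from a results table
#'
#' Rows are (patient, load case) observations, columns the per-level
#' compression and shear values; rows with any infeasible level are
#' excluded and counted in the \code{n_excluded} attribute.
#'
#' @param results simulation results table (long format).
#' @param config optional configuration tag to filter on.
#' @param response \code{"both"}, \code{"compression"} or \code{"shear"}.
#' @return Data frame with id columns \code{patient_id, config, load_case}
#'   and one numeric column per (level, response).
#' @export
build_load_matrix <- function(results, config = NULL,
                              response = c("both", "compression", "shear")) {
  response <- match.arg(response)
  r <- results
  if (!is.null(config)) r <- r[r$config %in% config, ]
  key <- interaction(r$patient_id, r$config, r$load_case, drop = TRUE)
  ok_key <- tapply(r$feasible, key, all)
  keep <- ok_key[as.character(key)]
  n_excl <- sum(!keep) / length(JOINT_LEVELS)
  r <- r[keep, ]
  ids <- unique(r[, c("patient_id", "config", "load_case")])
  wide <- ids
  for (lvl in JOINT_LEVELS) {
    sub <- r[r$level == lvl, ]
    i <- match(paste(wide$patient_id, wide$config, wide$load_case),
               paste(sub$patient_id, sub$config, sub$load_case))
    nm <- gsub("/", "_", lvl)
    if (response %in% c("both", "compression")) wide[[paste0("compr_", nm)]] <- sub$compression_N[i]
    if (response %in% c("both", "shear")) wide[[paste0("shear_", nm)]] <- sub$shear_AP_N[i]
  }
  rownames(wide) <- NULL
  structure(wide, n_excluded = n_excl)
}
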