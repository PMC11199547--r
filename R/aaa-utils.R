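#' @keywords internal
"_PACKAGE"

# Vertebral level bookkeeping shared across modules.
THORACIC_LEVELS <- paste0("T", 1:12)
LUMBAR_LEVELS <- paste0("L", 1:5)
ALL_LEVELS <- c(THORACIC_LEVELS, LUMBAR_LEVELS)

# Evaluated functional spinal units, cranial to caudal.
JOINT_LEVELS <- c("T12/L1", "L1/L2", "L2/L3", "L3/L4", "L4/L5", "L5/S1")

# Rigid bodies of the sagittal chain, caudal to cranial. The pelvis is ground;
# the thoracic spine and ribcage are fused into one block.
BODY_ORDER <- c("pelvis", "L5", "L4", "L3", "L2", "L1", "thorax")

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# z-component of the 2-D cross product r x f (x = anterior, y = superior).
cross2 <- function(rx, ry, fx, fy) rx * fy - ry * fx

# Run an expression with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Rigid body index (1-based along BODY_ORDER); vertebral levels map onto the
# chain, thoracic levels onto the fused block.
body_of_level <- function(level) {
  out <- ifelse(level %in% c("pelvis", "sacrum"), "pelvis",
    ifelse(level %in% THORACIC_LEVELS, "thorax", level)
  )
  bad <- !(out %in% BODY_ORDER)
  if (any(bad)) {
    stop("unknown attachment level(s): ", paste(unique(level[bad]), collapse = ", "))
  }
  out
}

body_index <- function(body) match(body, BODY_ORDER)

`%||%` <- function(a, b) if (is.null(a)) b else a
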