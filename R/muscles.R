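# Generic lumbar muscle architecture: straight point-to-point fascicles
# grouped into rectus abdominis (RA), internal/external oblique (IO/EO),
# psoas major (PM), quadratus lumborum (QL), multifidus (MF), longissimus
# thoracis pars lumborum (LTL), iliocostalis lumborum (IL) and
# interspinales (IS). Attachments are stored as offsets from vertebral
# frames (or the pelvic frame at the lumbosacral joint) for a reference
# torso height and scaled affinely with the individual geometry.

MUSCLE_GROUPS <- c("RA", "IO", "EO", "PM", "QL", "MF", "LTL", "IL", "IS")
MUSCLE_REF_TH <- 0.45

#' Read a muscle parameter table
#'
#' @param path CSV with columns \code{name, group, side, origin_level,
#'   origin_ap, origin_si, insertion_level, insertion_ap, insertion_si,
#'   pcsa_m2}. Levels are \code{pelvis} or vertebral names T1..L5; offsets
#'   are metres at the reference torso height of 0.45 m.
#' @return Validated data frame.
#' @export
read_muscle_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "group", "side", "origin_level", "origin_ap", "origin_si",
              "insertion_level", "insertion_ap", "insertion_si", "pcsa_m2")
  if (!all(needed %in% names(tab))) stop("muscle table misses columns")
  if (any(!tab$group %in% MUSCLE_GROUPS)) stop("unknown muscle group in table")
  if (any(tab$pcsa_m2 <= 0)) stop("PCSA must be positive")
  ok_level <- c("pelvis", ALL_LEVELS)
  if (any(!tab$origin_level %in% ok_level) || any(!tab$insertion_level %in% ok_level)) {
    stop("attachment level not part of the modeled chain")
  }
  tab
}

#' Bundled generic muscle table
#' @return The packaged default muscle parameter table (50 fascicles,
#'   both sides, all nine groups).
#' @export
default_muscle_table <- function() {
  read_muscle_table(system.file("extdata", "muscle_table.csv",
                                package = "spineload", mustWork = TRUE))
}

#' Attach muscle fascicles to an individual spine geometry
#'
#' Places each fascicle's origin and insertion by adding the tabulated
#' offsets, scaled affinely by \code{TH / 0.45}, to the respective
#' vertebral frame centre (or to the pelvic frame at the lumbosacral
#' joint). Fascicle count and PCSAs are geometry-independent: only the
#' attachment coordinates vary between individuals.
#'
#' @param geometry a \code{spine_geometry}.
#' @param muscle_table table as from \code{\link{default_muscle_table}}.
#' @return Data frame of fascicles with global (unposed) attachment
#'   coordinates \code{o_x, o_y, i_x, i_y}, attachment bodies
#'   \code{o_body, i_body}, and \code{pcsa_m2}.
#' @export
attach_muscles <- function(geometry, muscle_table = default_muscle_table()) {
  tab <- muscle_table
  s <- geometry$TH / MUSCLE_REF_TH
  lv <- geometry$levels
  frame_xy <- function(level) {
    if (level == "pelvis") return(c(0, 0))
    r <- lv[lv$level == level, ]
    if (nrow(r) == 0) stop("attachment references missing level: ", level)
    c(r$cx, r$cy)
  }
  o <- t(vapply(seq_len(nrow(tab)), function(i) {
    frame_xy(tab$origin_level[i]) + s * c(tab$origin_ap[i], tab$origin_si[i])
  }, numeric(2)))
  ins <- t(vapply(seq_len(nrow(tab)), function(i) {
    frame_xy(tab$insertion_level[i]) + s * c(tab$insertion_ap[i], tab$insertion_si[i])
  }, numeric(2)))
  out <- data.frame(name = tab$name, group = tab$group, side = tab$side,
                    o_body = body_of_level(tab$origin_level),
                    o_x = o[, 1], o_y = o[, 2],
                    i_body = body_of_level(tab$insertion_level),
                    i_x = ins[, 1], i_y = ins[, 2],
                    pcsa_m2 = tab$pcsa_m2, stringsAsFactors = FALSE)
  same <- abs(out$o_x - out$i_x) < 1e-12 & abs(out$o_y - out$i_y) < 1e-12
  if (any(same)) stop("fascicle with coincident origin and insertion")
  out
}
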