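#' Write / read a tuning map as plain-text TSV matrices plus JSON metadata
#'
#' The map is stored as `<path>.json` (pixel size, stage, parameters) plus
#' TSV matrices `<path>_re.tsv`, `<path>_im.tsv` (real and imaginary parts
#' of `z`), `<path>_valid.tsv` and, when present, `<path>_kpref.tsv`.
#'
#' @param map a [tuning_map()].
#' @param path base path (without suffix).
#' @return `write_map` returns `path` invisibly; `read_map` the
#'   reconstructed [tuning_map()].
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "tuning_map"))
  wm <- function(m, suffix) {
    write.table(format(m, digits = 10, trim = TRUE, scientific = TRUE),
                paste0(path, suffix), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  wm(Re(map$z), "_re.tsv")
  wm(Im(map$z), "_im.tsv")
  wm(map$valid * 1L, "_valid.tsv")
  if (!is.null(map$kpref)) wm(map$kpref, "_kpref.tsv")
  jsonlite::write_json(
    list(px_mm = map$px_mm, stage = map$stage,
         dim = dim(map$z), has_kpref = !is.null(map$kpref),
         params = map$params,
         software = paste("moiremap",
                          as.character(utils::packageVersion("moiremap")))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rm_ <- function(suffix) {
    m <- as.matrix(read.table(paste0(path, suffix), sep = "\t",
                              header = FALSE))
    dimnames(m) <- NULL
    m
  }
  z <- matrix(complex(real = rm_("_re.tsv"), imaginary = rm_("_im.tsv")),
              meta$dim[1], meta$dim[2])
  kpref <- if (isTRUE(meta$has_kpref)) rm_("_kpref.tsv") else NULL
  valid <- rm_("_valid.tsv") > 0
  tuning_map(z = z, px_mm = meta$px_mm, stage = meta$stage, kpref = kpref,
             valid = valid, params = as.list(meta$params))
}

#' Write pinwheels and layout statistics to plain-text outputs
#'
#' `write_pinwheels` writes a TSV with columns `x_mm`, `y_mm`, `charge`,
#' `degenerate`, `confidence`; `write_stats_json` a JSON file with the six
#' common-design parameters.
#'
#' @param set a [pinwheel_set()].
#' @param stats a [compute_common_design_stats()] result.
#' @param path output file path.
#' @export
write_pinwheels <- function(set, path) {
  df <- data.frame(x_mm = set$x, y_mm = set$y, charge = set$charge,
                   degenerate = set$degenerate,
                   confidence = set$confidence)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pinwheels
#' @export
write_stats_json <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
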