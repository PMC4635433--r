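#' Read a biome parameter table
#'
#' Reads a delimited parameter table (one row per biome) and validates every
#' row, reporting all violations at once. Required columns: \code{biome},
#' \code{forest}, \code{b_leaf}, \code{b_wood}, \code{b_froot},
#' \code{b_croot}, \code{LN}, \code{Lleaf}, \code{Lfroot}, \code{Lwood},
#' \code{c_1} ... \code{c_13}.
#'
#' @param path path to a CSV file
#' @return named list of \code{\link{biome_params}}, keyed by biome code
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("parameter table not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("biome", "forest", "b_leaf", "b_wood", "b_froot", "b_croot",
                "LN", "Lleaf", "Lfroot", "Lwood", paste0("c_", 1:13))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("parameter table missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  num_cols <- setdiff(required, c("biome", "forest"))
  problems <- character(0)
  out <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    bad_num <- num_cols[!vapply(row[num_cols],
                                function(v) is.numeric(v) && is.finite(v),
                                logical(1))]
    if (length(bad_num)) {
      problems <- c(problems, sprintf(
        "row %d (%s): non-numeric value in %s", i, row$biome,
        paste(bad_num, collapse = ", ")))
      next
    }
    ps <- tryCatch(
      biome_params(row$biome,
                   b = as.numeric(row[c("b_leaf", "b_wood",
                                        "b_froot", "b_croot")]),
                   LN = row$LN, Lleaf = row$Lleaf, Lfroot = row$Lfroot,
                   Lwood = row$Lwood,
                   c = as.numeric(row[paste0("c_", 1:13)]),
                   forest = as.logical(row$forest)),
      error = function(e) conditionMessage(e))
    if (is.character(ps))
      problems <- c(problems, sprintf("row %d (%s): %s", i, row$biome, ps))
    else out[[row$biome]] <- ps
  }
  if (length(problems))
    stop(paste(c("invalid parameter table:", problems), collapse = "\n  "),
         call. = FALSE)
  out
}

#' Write a biome parameter table
#'
#' Inverse of \code{\link{read_parameter_table}}; the round trip preserves
#' all values.
#'
#' @param params named list of \code{\link{biome_params}}
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
write_parameter_table <- function(params, path) {
  rows <- lapply(params, function(p) {
    data.frame(biome = p$biome, forest = p$forest,
               b_leaf = p$b[1], b_wood = p$b[2],
               b_froot = p$b[3], b_croot = p$b[4],
               LN = p$LN, Lleaf = p$Lleaf, Lfroot = p$Lfroot,
               Lwood = p$Lwood,
               as.data.frame(as.list(stats::setNames(p$c,
                                                     paste0("c_", 1:13)))))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default biome parameter table
#'
#' The parameter table shipped with the package: 13 IGBP-style biomes with
#' plausible, calibratable allocation fractions, litter chemistry and
#' potential turnover rates, constrained so that baseline residence times
#' fall in roughly 12--54 years for forest biomes and 4--6 years for
#' non-forest biomes under the default soil texture. Values are editable
#' defaults, not measurements.
#'
#' @return named list of \code{\link{biome_params}}
#' @export
default_parameter_table <- function() {
  path <- system.file("extdata", "biome_parameters.csv",
                      package = "carbotrace", mustWork = TRUE)
  read_parameter_table(path)
}

#' Default soil texture
#'
#' Loam-like reference texture used when no per-cell texture is supplied
#' (clay 0.20, silt 0.40, sand 0.40, porosity 0.45).
#'
#' @return a \code{\link{soil_texture}}
#' @export
default_soil_texture <- function() {
  soil_texture(clay = 0.20, silt = 0.40, sand = 0.40, porosity = 0.45)
}
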