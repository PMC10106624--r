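#' Primer pair constructor
#'
#' A named forward/reverse oligo pair, both written 5'->3', with a role in
#' the multiplex assay: `male_specific` pairs anneal only in the
#' male-specific region of chromosome Y, `control` pairs target an autosome
#' so every successful reaction yields at least one band.
#'
#' @param name Pair name.
#' @param forward,reverse Oligo sequences, 5'->3', ACGT alphabet.
#' @param role `"male_specific"` or `"control"`.
#' @param expected_length Optional expected product length in bp (reporting
#'   only; never used for the sex call).
#' @return A list of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse,
                        role = c("control", "male_specific"),
                        expected_length = NULL) {
  role <- match.arg(role)
  forward <- toupper(forward)
  reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (!nzchar(p) || grepl("[^ACGT]", p)) {
      stop("primers must be nonempty ACGT strings, got: ", p, call. = FALSE)
    }
  }
  structure(list(name = name, forward = forward, reverse = reverse,
                 role = role, expected_length = expected_length),
            class = "primer_pair")
}

#' Assay definition constructor
#'
#' @param marker_panel A [marker_panel()] for the RNA-seq arm.
#' @param primer_pairs List of [primer_pair()] objects for the PCR arm;
#'   for multiplex calling there must be exactly one `male_specific` pair
#'   and at least one `control` pair.
#' @return A list of class `assay_definition`.
#' @export
assay_definition <- function(marker_panel, primer_pairs) {
  stopifnot(inherits(marker_panel, "marker_panel"))
  roles <- vapply(primer_pairs, `[[`, character(1L), "role")
  if (sum(roles == "male_specific") != 1L || sum(roles == "control") < 1L) {
    stop("multiplex assay needs exactly one male_specific pair and at ",
         "least one control pair", call. = FALSE)
  }
  names(primer_pairs) <- vapply(primer_pairs, `[[`, character(1L), "name")
  structure(list(panel = marker_panel, primer_pairs = primer_pairs),
            class = "assay_definition")
}

# Minimal reader for the TOML dialect used by assay/run configs: [table]
# and [[array-of-tables]] headers, and key = value lines where the value is
# a quoted string, number, boolean, or a flat array of those. No installed
# package parses TOML, and the dialect needed here is tiny.
parse_toml_value <- function(raw) {
  raw <- trimws(raw)
  if (grepl("^\\[", raw)) {
    inner <- sub("^\\[", "", sub("\\]$", "", raw))
    if (!nzchar(trimws(inner))) return(list())
    parts <- strsplit(inner, ",")[[1L]]
    return(unlist(lapply(parts, parse_toml_value)))
  }
  if (grepl('^".*"$', raw)) return(gsub('^"|"$', "", raw))
  if (raw %in% c("true", "false")) return(raw == "true")
  num <- suppressWarnings(as.numeric(raw))
  if (!is.na(num)) return(num)
  raw
}

#' Read a key-value (TOML-dialect) config file
#'
#' Supports `[table]` sections, repeated `[[table]]` sections (collected
#' into a list), and scalar/array values. Sufficient for assay and pipeline
#' configs; not a general TOML implementation.
#'
#' @param path Config file path.
#' @return A nested named list.
#' @export
read_toml_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  cur <- NULL      # name of current table
  cur_arr <- FALSE # current table is one element of an array of tables
  for (ln in lines) {
    if (grepl("^\\[\\[.+\\]\\]$", ln)) {
      cur <- gsub("^\\[\\[|\\]\\]$", "", ln)
      cur_arr <- TRUE
      if (is.null(out[[cur]])) out[[cur]] <- list()
      out[[cur]][[length(out[[cur]]) + 1L]] <- list()
    } else if (grepl("^\\[.+\\]$", ln)) {
      cur <- gsub("^\\[|\\]$", "", ln)
      cur_arr <- FALSE
      if (is.null(out[[cur]])) out[[cur]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- parse_toml_value(sub("^[^=]*=", "", ln))
      if (is.null(cur)) {
        out[[key]] <- val
      } else if (cur_arr) {
        out[[cur]][[length(out[[cur]])]][[key]] <- val
      } else {
        out[[cur]][[key]] <- val
      }
    } else {
      stop("cannot parse config line: ", ln, call. = FALSE)
    }
  }
  out
}

#' Read an assay definition from a config file
#'
#' Expects a `[panel]` table (`genes`, `tau_female`, `tau_male`) and one or
#' more `[[primer_pairs]]` tables (`name`, `forward`, `reverse`, `role`,
#' optional `expected_length`).
#'
#' @param path Config path, or the name of a bundled assay
#'   (`"bovine_chrY"`).
#' @return An [assay_definition()].
#' @export
read_assay_definition <- function(path) {
  if (!file.exists(path)) {
    bundled <- system.file("extdata", paste0(path, ".toml"),
                           package = "chrysexer")
    if (nzchar(bundled)) path <- bundled
    else stop("assay config not found: ", path, call. = FALSE)
  }
  cfg <- read_toml_config(path)
  if (is.null(cfg$panel) || is.null(cfg$primer_pairs)) {
    stop("assay config needs [panel] and [[primer_pairs]]", call. = FALSE)
  }
  panel <- marker_panel(cfg$panel$genes,
                        tau_female = cfg$panel$tau_female,
                        tau_male = cfg$panel$tau_male)
  pairs <- lapply(cfg$primer_pairs, function(p) {
    primer_pair(p$name, p$forward, p$reverse, role = p$role,
                expected_length = p$expected_length)
  })
  assay_definition(panel, pairs)
}

#' The bundled bovine chromosome-Y sexing assay
#'
#' The default assay couples the four-gene RNA-seq marker panel with the
#' published multiplex primer set: an MSY pair
#' (F 5'-AGGGTGAAGCAAATGGTCGT-3', R 5'-GGAGCAACAGTGTCCTGTGT-3') annealing
#' in non-repeated male-specific chromosome-Y sequence, and an autosomal
#' CDK1 control pair (F 5'-GCCCAGACCCAGCATCATT-3',
#' R 5'-GGGAGTGCCCAAAGCTCTAAA-3') on chromosome 28.
#'
#' @return An [assay_definition()].
#' @export
default_assay <- function() {
  read_assay_definition(system.file("extdata", "bovine_chrY.toml",
                                    package = "chrysexer", mustWork = TRUE))
}
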