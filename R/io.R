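#' Read and write pedigree files
#'
#' A pedigree file has three columns `animal sire dam` (whitespace- or
#' comma-separated; header optional; 0 = unknown parent). On read the
#' pedigree is validated and topologically sorted, and the id -> index map
#' is attached as attribute `id_index`.
#'
#' @param path file path.
#' @return A validated pedigree tibble.
#' @export
read_pedigree <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- {
    toks <- strsplit(trimws(first),
                     if (sep == ",") "," else "[[:space:]]+")[[1]]
    suppressWarnings(any(is.na(as.numeric(toks))))
  }
  df <- if (has_header) {
    read.table(path, sep = sep, header = TRUE, strip.white = TRUE)
  } else {
    read.table(path, sep = sep, header = FALSE, strip.white = TRUE,
               col.names = c("animal", "sire", "dam"))
  }
  names(df)[1:3] <- c("animal", "sire", "dam")
  ped <- tryCatch(ped_validate(df[, 1:3]),
                  error = function(e) {
                    abort(paste0("invalid pedigree file '", path, "': ",
                                 conditionMessage(e)))
                  })
  ped
}

#' @rdname read_pedigree
#' @param pedigree pedigree data frame.
#' @export
write_pedigree <- function(pedigree, path) {
  readr::write_csv(pedigree[, c("animal", "sire", "dam")], path)
  invisible(path)
}

#' Read and write phenotype files
#'
#' CSV with column `animal`, one column per fixed factor, and the trait
#' column. Factor columns are read as character and converted by the model
#' builder.
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"animal" %in% names(df)) {
    abort(paste0("phenotype file '", path, "' lacks an 'animal' column"))
  }
  df
}

#' @rdname read_phenotypes
#' @param phenotypes phenotype data frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_csv(phenotypes, path)
  invisible(path)
}

#' Write stored draws and a run manifest
#'
#' Draws go to CSV (one row per stored iteration); the manifest is a JSON
#' echo of the configuration (sampler, iteration counts, seed, adaptation
#' report) for archival reproducibility.
#'
#' @param fit an `animal_fit`.
#' @param draws_path,manifest_path output paths (`NULL` to skip one).
#' @export
write_fit <- function(fit, draws_path, manifest_path = NULL) {
  readr::write_csv(fit$draws, draws_path)
  if (!is.null(manifest_path)) {
    manifest <- list(
      sampler = fit$sampler, n_iter = fit$n_iter, burn_in = fit$burn_in,
      seed = fit$seed, n = fit$n, p = fit$p, q = fit$q,
      control = fit$control,
      report = fit$report[setdiff(names(fit$report),
                                  c("eps_trace", "depth_table", "a_draws"))],
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("pedmcmc"))
    )
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, force = TRUE)
  }
  invisible(fit)
}
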