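# Plain-text serialization of the pipeline's artifacts: cohorts as CSV,
# networks as a line-oriented node/levels/parents/CPT format, images as
# plain (P2) portable graymaps.

#' Read and write cohort tables
#'
#' Comma-separated text with a header row, UTF-8, "." decimal.
#'
#' @param cohort data.frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = TRUE)
}

#' Read and write a network as plain text
#'
#' One block per node: its name, level labels, parent list and CPT rows
#' (full precision, one row per parent configuration).
#'
#' @param net a [bn] with CPTs.
#' @param path file path.
#' @export
write_network <- function(net, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("prognet-network 1", con)
  if (!is.null(net$outcome)) writeLines(paste("outcome", net$outcome), con)
  for (v in net$nodes) {
    writeLines(paste("node", v), con)
    writeLines(paste("levels", paste(net$levels[[v]], collapse = "\t")), con)
    writeLines(paste("parents", paste(net$parents[[v]], collapse = "\t")), con)
    if (!is.null(net$cpts)) {
      for (r in seq_len(nrow(net$cpts[[v]])))
        writeLines(paste("cpt", paste(sprintf("%.17g", net$cpts[[v]][r, ]),
                                      collapse = "\t")), con)
    }
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!startsWith(lines[1], "prognet-network"))
    stop("not a prognet network file")
  outcome <- NULL
  levels <- list(); parents <- list(); cpts <- list()
  cur <- NULL
  for (ln in lines[-1]) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    key <- parts[1]
    if (key == "outcome") outcome <- parts[2]
    else if (key == "node") { cur <- parts[2]; cpts[[cur]] <- NULL }
    else if (key == "levels") levels[[cur]] <- parts[-1]
    else if (key == "parents") parents[[cur]] <-
        if (length(parts) > 1) parts[-1] else character(0)
    else if (key == "cpt") cpts[[cur]] <-
        rbind(cpts[[cur]], as.numeric(parts[-1]))
  }
  bn(levels, parents, if (length(cpts)) cpts else NULL, outcome = outcome)
}

#' Read and write plain portable graymaps (PGM, P2)
#'
#' @param img matrix of intensities in [0, 255] (rounded on write).
#' @param path file path.
#' @export
write_pgm <- function(img, path) {
  if (!is.matrix(img)) stop("img must be a matrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  write(t(round(pmin(pmax(img, 0), 255))), con, ncolumns = ncol(img))
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("only plain (P2) PGM is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}
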