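## Minimal STAR-format tables (the metadata dialect of the cryo-EM
## ecosystem): one data block with a loop_ of named columns.

#' Write a data.frame as a STAR loop block
#'
#' @param df a data.frame; column names become `_cryored<Name>` tags.
#' @param path output path.
#' @param block data block name.
#' @return `path`, invisibly.
#' @export
writeStarTable <- function(df, path, block = "cryored") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("data_%s", block), "", "loop_"), con)
  nms <- names(df)
  writeLines(sprintf("_cryored%s #%d", toupper(substring(nms, 1, 1)) |>
                       paste0(substring(nms, 2)), seq_along(nms)), con)
  apply(df, 1, function(row)
    writeLines(paste(format(row, trim = TRUE, digits = 15),
                     collapse = " "), con))
  invisible(path)
}

#' Read a STAR loop block into a data.frame
#'
#' @param path STAR file path.
#' @param block data block name to read (default: first block found).
#' @return data.frame with the loop's columns (numeric where possible).
#' @export
readStarTable <- function(path, block = NULL) {
  lines <- trimws(readLines(path))
  if (!is.null(block)) {
    start <- which(lines == sprintf("data_%s", block))
    if (!length(start)) stop(sprintf("block 'data_%s' not found", block))
  } else {
    start <- grep("^data_", lines)[1]
    if (is.na(start)) stop("no data block found")
  }
  i <- start + 1L
  while (i <= length(lines) && lines[i] != "loop_") i <- i + 1L
  if (i > length(lines)) stop("no loop_ in block")
  i <- i + 1L
  tags <- character(0)
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    tags <- c(tags, sub("^_cryored", "", sub("\\s+#\\d+$", "", lines[i])))
    i <- i + 1L
  }
  rows <- list()
  while (i <= length(lines) && nzchar(lines[i]) &&
         !startsWith(lines[i], "data_")) {
    rows[[length(rows) + 1L]] <- strsplit(lines[i], "\\s+")[[1]]
    i <- i + 1L
  }
  if (!length(rows)) {
    df <- as.data.frame(matrix(nrow = 0, ncol = length(tags)))
  } else {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  }
  names(df) <- paste0(tolower(substring(tags, 1, 1)), substring(tags, 2))
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(num) || all(is.na(num) == (df[[j]] %in% c("NA", "NaN"))))
      df[[j]] <- num
  }
  df
}
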