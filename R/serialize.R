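# Descriptor serialization: CSV (header of canonical names, one row per
# complex, 17 significant digits so values round-trip bit-exactly) and
# JSON (layout + values + provenance).

#' Write descriptor vectors to CSV or JSON
#'
#' @param vectors a DescriptorVector or list of them (one variant only)
#' @param path output file
#' @param format "csv" or "json"
#' @return invisibly, the path
#' @export
writeDescriptors <- function(vectors, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (is(vectors, "DescriptorVector")) vectors <- list(vectors)
  variants <- unique(vapply(vectors, descriptorVariant, character(1)))
  if (length(variants) > 1) {
    stop("mixed descriptor variants in one file: ",
         paste(variants, collapse = ", "))
  }
  if (format == "csv") {
    if (!length(vectors)) {
      writeLines("id", path)
      return(invisible(path))
    }
    header <- c("id", descriptorLayoutOf(vectors[[1]])$name)
    rows <- vapply(vectors, function(v) {
      paste(c(shQuoteCSV(v@provenance$complex_id),
              sprintf("%.17g", unname(descriptorValues(v)))),
            collapse = ",")
    }, character(1))
    writeLines(c(paste(shQuoteCSV(header), collapse = ","), rows), path)
  } else {
    payload <- lapply(vectors, function(v) {
      list(provenance = v@provenance,
           layout = descriptorLayoutOf(v),
           values = unname(descriptorValues(v)))
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

shQuoteCSV <- function(x) {
  needs <- grepl("[,\"]", x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Read a descriptor CSV written by \code{\link{writeDescriptors}}
#'
#' @param path CSV path
#' @return data.frame with id column and one numeric column per entry
#' @export
readDescriptorsCSV <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Export a descriptor layout as JSON
#'
#' @param variant "GRADE" or "XGRADE"
#' @param path output path
#' @return invisibly, the path
#' @export
writeLayoutJSON <- function(variant, path) {
  jsonlite::write_json(descriptorLayout(variant), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
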