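# internal helpers: delimiter sniffing, seeded evaluation, provenance hash

detect_delim <- function(path) {
    header <- readLines(path, n = 1L)
    if (grepl("\t", header)) "\t" else ","
}

# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# deterministic child seed, kept inside 32-bit integer range
derive_seed <- function(seed, index) {
    as.integer((as.numeric(seed) * 48271 + 99991 * as.numeric(index)) %%
        2147483629)
}

# polynomial rolling hash over a character serialization; provenance only
config_hash <- function(x) {
    bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
    h <- 5381
    for (b in bytes) h <- (h * 33 + b) %% 2147483647
    sprintf("%08x", h)
}

# comment-line provenance header written at the top of every output file
provenance_header <- function(seed, cfg = NULL, timestamp = TRUE) {
    c(sprintf("# FDGnet %s", as.character(utils::packageVersion("FDGnet"))),
      sprintf("# seed: %s", if (is.null(seed)) "NA" else seed),
      if (!is.null(cfg)) sprintf("# config: %s", config_hash(cfg)),
      if (timestamp) sprintf("# written: %s",
          format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}

write_delim_with_header <- function(df, path, header_lines, sep = "\t",
                                    row.names = FALSE) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header_lines, con)
    utils::write.table(df, con, sep = sep, quote = FALSE,
        row.names = row.names, col.names = TRUE)
    invisible(path)
}
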