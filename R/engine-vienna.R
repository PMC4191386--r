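# Delegation layer to ViennaRNA. A batch of operations is serialized to a
# JSON request file and executed by the bundled worker script in one python
# process, which keeps per-call interpreter startup off the hot path.

vienna_python <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found for the ViennaRNA backend",
                        call. = FALSE)
  py
}

vienna_worker <- function() {
  path <- system.file("python", "vienna_worker.py", package = "ribodesign")
  if (!nzchar(path)) stop("vienna_worker.py not found in the installed package",
                          call. = FALSE)
  path
}

vienna_call <- function(ops, engine) {
  req <- list(
    params = engine$params,
    temperature = engine$temperature,
    dangles = engine$dangles,
    ops = unname(ops) # named lists would serialize as JSON objects
  )
  req_file <- tempfile(fileext = ".json")
  on.exit(unlink(req_file), add = TRUE)
  jsonlite::write_json(req, req_file, auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(
    system2(vienna_python(), c(vienna_worker(), req_file),
            stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("ViennaRNA worker failed (exit ", status, ")", call. = FALSE)
  }
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}
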