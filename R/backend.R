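# Bridge to the bundled RDKit batch worker. Requests and responses are
# JSON files exchanged with a short-lived python process; everything is
# batched so a whole compound library costs a handful of calls.

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "molfrag")
  if (!nzchar(path)) {
    # during devtools::load_all() the file sits under inst/
    path <- system.file("inst", "python", "chem_backend.py", package = "molfrag")
  }
  if (!nzchar(path)) stop("chem_backend.py not found in the molfrag installation")
  path
}

backend_python <- function() Sys.getenv("MOLFRAG_PYTHON", unset = "python")

#' @keywords internal
chem_backend <- function(request) {
  infile <- tempfile("molfrag_req_", fileext = ".json")
  outfile <- tempfile("molfrag_res_", fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(request, infile, auto_unbox = TRUE, digits = NA, null = "null")
  log <- suppressWarnings(
    system2(backend_python(), c(backend_script(), infile, outfile),
            stdout = TRUE, stderr = TRUE)
  )
  status <- attr(log, "status")
  if ((!is.null(status) && status != 0) || !file.exists(outfile)) {
    stop("chemistry backend failed: ", paste(log, collapse = "\n"))
  }
  jsonlite::read_json(outfile, simplifyVector = FALSE)
}

# analyze a batch of SMILES against a batch of two-atom SMARTS patterns
chem_analyze <- function(smiles, smarts = character()) {
  chem_backend(list(op = "analyze", smiles = I(as.list(smiles)),
                    smarts = I(as.list(smarts))))
}

chem_check_rules <- function(smarts) {
  chem_backend(list(op = "check_rules", smarts = I(as.list(smarts))))
}

chem_assemble <- function(parents, jobs) {
  chem_backend(list(op = "assemble", parents = I(as.list(parents)), jobs = jobs))
}

chem_props <- function(smiles) {
  chem_backend(list(op = "props", smiles = I(as.list(smiles))))
}

chem_canonical <- function(smiles) {
  chem_backend(list(op = "canonical", smiles = I(as.list(smiles))))
}

chem_substructure <- function(parent, frag) {
  pairs <- purrr::map2(parent, frag, function(p, f) list(parent = p, frag = f))
  res <- chem_backend(list(op = "substructure", pairs = pairs))
  purrr::map_lgl(res, function(r) isTRUE(r$ok) && isTRUE(r$is_sub))
}

# tidy view of one analyzed molecule's bond list
bond_table <- function(mol) {
  if (length(mol$bonds) == 0) {
    return(tibble::tibble(index = integer(), a = integer(), b = integer(),
                          order = character(), ring = logical()))
  }
  tibble::tibble(
    index = purrr::map_int(mol$bonds, "index"),
    a = purrr::map_int(mol$bonds, "a"),
    b = purrr::map_int(mol$bonds, "b"),
    order = purrr::map_chr(mol$bonds, "order"),
    ring = purrr::map_lgl(mol$bonds, "ring")
  )
}
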