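# The service layer: a framework-neutral HTTP request router carrying the
# wire contract (routes, status codes, content types, structured error
# bodies), a minimal blocking HTTP server over base-R sockets, and the
# command-line interface. The service is read-only: no route mutates the
# store, and every payload is byte-identical to the corresponding direct
# query-module call.

json_body <- function(x) {
  if (inherits(x, "vb_payload")) vb_to_json(x)
  else as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     null = "null"))
}

http_response <- function(status, body, content_type = "application/json") {
  list(status = as.integer(status), content_type = content_type, body = body)
}

error_body <- function(error, message)
  json_body(list(error = error, message = message))

#' Route an HTTP-style request against a store
#'
#' Implements the browser API contract:
#' `GET /api/search?q=...`, `/api/autocomplete?q=...`, `/api/gene/{id}`,
#' `/api/transcript/{id}`, `/api/variant/{chrom-pos-ref-alt}`,
#' `/api/region/{chrom}-{start}-{stop}` and
#' `/api/gene/{id}/variants.csv`. All routes return JSON except the CSV
#' export; unknown entities yield 404 with a structured body, malformed
#' variant keys 400, and over-limit regions 422 naming the limit.
#'
#' @param store a `vb_store`
#' @param method HTTP method (only GET is served)
#' @param path request path
#' @param query named list of query parameters
#' @return list(status, content_type, body)
#' @export
handle_request <- function(store, method, path, query = list()) {
  if (!identical(toupper(method), "GET"))
    return(http_response(405, error_body("method_not_allowed",
                                         "only GET is supported")))
  path <- sub("\\?.*$", "", path)
  parts <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  if (length(parts) < 2L || parts[1] != "api")
    return(http_response(404, error_body("not_found",
                                         sprintf("no route for '%s'", path))))
  route <- parts[2]
  arg <- if (length(parts) >= 3L) utils::URLdecode(parts[3]) else NULL

  if (route == "search") {
    q <- query$q
    if (is.null(q) || !nzchar(trimws(q)))
      return(http_response(400, error_body("bad_request",
                                           "missing query parameter q")))
    return(http_response(200, json_body(unclass(resolve_search(q, store)))))
  }
  if (route == "autocomplete") {
    q <- query$q
    if (is.null(q) || !nzchar(trimws(q)))
      return(http_response(400, error_body("bad_request",
                                           "missing query parameter q")))
    return(http_response(200, json_body(list(
      suggestions = as.list(autocomplete(q, store))))))
  }
  if (route == "gene" && !is.null(arg)) {
    if (length(parts) == 4L && parts[4] == "variants.csv") {
      payload <- gene_page(arg, store)
      if (payload$page_kind == "not_found")
        return(http_response(404, error_body("not_found",
                                             sprintf("gene '%s' not found", arg))))
      return(http_response(200,
                           export_variant_table_csv(payload,
                                                    store$config$populations),
                           content_type = "text/csv"))
    }
    payload <- gene_page(arg, store)
    status <- if (payload$page_kind == "not_found") 404L else 200L
    return(http_response(status, json_body(payload)))
  }
  if (route == "transcript" && !is.null(arg)) {
    payload <- transcript_page(arg, store)
    status <- if (payload$page_kind == "not_found") 404L else 200L
    return(http_response(status, json_body(payload)))
  }
  if (route == "variant" && !is.null(arg)) {
    payload <- tryCatch(variant_page(arg, store), error = function(e)
      http_response(400, error_body("bad_request", conditionMessage(e))))
    if (!inherits(payload, "vb_payload")) return(payload)
    status <- if (payload$page_kind == "not_found") 404L else 200L
    return(http_response(status, json_body(payload)))
  }
  if (route == "region" && !is.null(arg)) {
    m <- regmatches(arg, regexec("^((?:chr)?[0-9XYMT]+)-([0-9]+)-([0-9]+)$", arg))[[1]]
    if (length(m) != 4L)
      return(http_response(400, error_body(
        "bad_request", "expected region as chrom-start-stop")))
    payload <- tryCatch(
      region_page(m[2], as.integer(m[3]), as.integer(m[4]), store),
      error = function(e)
        http_response(400, error_body("bad_request", conditionMessage(e))))
    if (!inherits(payload, "vb_payload")) return(payload)
    if (isTRUE(payload$metadata$rejected))
      return(http_response(422, json_body(payload)))
    return(http_response(200, json_body(payload)))
  }
  http_response(404, error_body("not_found", sprintf("no route for '%s'", path)))
}

parse_query_string <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  pairs <- strsplit(qs, "&", fixed = TRUE)[[1]]
  out <- list()
  for (p in pairs) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    out[[utils::URLdecode(kv[1])]] <-
      if (length(kv) > 1L) utils::URLdecode(chartr("+", " ", kv[2])) else ""
  }
  out
}

#' Serve the browser API over HTTP
#'
#' A minimal single-threaded HTTP/1.0 server over base-R sockets, routing
#' every request through [handle_request()]. Intended for local use and
#' testing; production deployments should put the router behind a proper
#' server.
#'
#' @param store_path directory written by [store_save()]
#' @param host bind address (default 127.0.0.1)
#' @param port TCP port
#' @param max_requests stop after this many requests (Inf = run forever);
#'   finite values support testing
#' @return number of requests served, invisibly
#' @export
serve <- function(store_path, host = "127.0.0.1", port = 8000L,
                  max_requests = Inf) {
  store <- store_load(store_path)   # errors when the store is missing
  sock <- serverSocket(port)
  on.exit(close(sock), add = TRUE)
  served <- 0
  while (served < max_requests) {
    con <- socketAccept(sock, blocking = TRUE, open = "r+b")
    req <- readLines(con, n = 1L, warn = FALSE)
    # drain headers
    repeat {
      h <- readLines(con, n = 1L, warn = FALSE)
      if (length(h) == 0L || !nzchar(trimws(h))) break
    }
    m <- strsplit(trimws(req), " ", fixed = TRUE)[[1]]
    resp <- if (length(m) >= 2L) {
      url <- strsplit(m[2], "?", fixed = TRUE)[[1]]
      handle_request(store, m[1], url[1],
                     parse_query_string(if (length(url) > 1L) url[2] else ""))
    } else http_response(400, error_body("bad_request", "malformed request line"))
    body_raw <- charToRaw(resp$body)
    writeLines(c(sprintf("HTTP/1.0 %d %s", resp$status,
                         if (resp$status == 200L) "OK" else "Error"),
                 sprintf("Content-Type: %s", resp$content_type),
                 sprintf("Content-Length: %d", length(body_raw)),
                 "Connection: close", ""), con, sep = "\r\n")
    writeBin(body_raw, con)
    flush(con)
    close(con)
    served <- served + 1
  }
  invisible(served)
}

cli_usage <- "usage: varbrowse <command> [options]

commands:
  build            --vcf F --gtf F --coverage F --out DIR
                   [--constraint F] [--cnv F] [--dbsnp F] [--carriers F]
                   [--aliases F]
  serve            --store DIR [--host H] [--port P]
  search           --store DIR QUERY
  export-csv       --store DIR GENE [--out F]
  readviz-manifest --store DIR --out F [--batch-size N]
  simulate         --seed N --out DIR [--n-genes N] [--variants-per-gene N]
"

cli_args <- function(argv) {
  opts <- list(); pos <- character()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      opts[[substring(a, 3)]] <- argv[i + 1L]
      i <- i + 2L
    } else {
      pos <- c(pos, a); i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

#' Command-line entry point
#'
#' Subcommands: `build` (ingest inputs into a store directory), `serve`
#' (HTTP API over a built store), `search` (offline search, prints the
#' resolved target), `export-csv` (gene variant table as CSV),
#' `readviz-manifest` (read-support manifest TSV for every variant) and
#' `simulate` (write a seeded synthetic fixture bundle). Returns a shell
#' exit code; errors print to stderr.
#'
#' @param argv character vector of arguments (excluding the program name)
#' @return integer exit code (0 on success, 2 on usage error)
#' @export
cli_main <- function(argv) {
  if (length(argv) == 0L) { message(cli_usage); return(2L) }
  cmd <- argv[1]
  parsed <- cli_args(argv[-1])
  o <- parsed$opts
  run <- function(expr) tryCatch({ expr; 0L }, error = function(e) {
    message("error: ", conditionMessage(e)); 1L
  })
  switch(cmd,
    build = run({
      store <- build_store(o$vcf, o$gtf, o$coverage,
                           constraint_path = o$constraint, cnv_path = o$cnv,
                           dbsnp_path = o$dbsnp, carriers_path = o$carriers,
                           alias_path = o$aliases)
      store <- precompute_large_gene_payloads(store)
      store_save(store, o$out)
      message("store written to ", o$out)
    }),
    serve = run(serve(o$store, host = o$host %||% "127.0.0.1",
                      port = as.integer(o$port %||% "8000"))),
    search = run({
      store <- store_load(o$store)
      res <- resolve_search(parsed$pos[1], store)
      cat(res$kind, res$target, "\n")
    }),
    `export-csv` = run({
      store <- store_load(o$store)
      csv <- export_variant_table_csv(gene_page(parsed$pos[1], store),
                                      store$config$populations)
      if (is.null(o$out)) cat(csv) else writeLines(sub("\n$", "", csv), o$out)
    }),
    `readviz-manifest` = run({
      store <- store_load(o$store)
      manifests <- lapply(names(store$variants), function(k) {
        cc <- store$carriers[variant_key == k]
        samples <- lapply(seq_len(nrow(cc)), function(i)
          readviz_sample(cc$sample_id[i], cc$genotype_class[i],
                         cc$gq[i], cc$dp[i]))
        build_manifest(store$variants[[k]], select_samples(samples),
                       window_width = store$config$window_width)
      })
      batches <- batch_manifests(manifests,
                                 as.integer(o$`batch-size` %||% "1000"))
      write_manifest_tsv(batches, o$out)
      message("manifest written to ", o$out)
    }),
    simulate = run({
      generate_fixtures(as.integer(o$seed), o$out,
                        n_genes = as.integer(o$`n-genes` %||% "4"),
                        variants_per_gene =
                          as.integer(o$`variants-per-gene` %||% "24"))
      message("fixtures written to ", o$out)
    }),
    { message("unknown subcommand '", cmd, "'\n", cli_usage); 2L }
  )
}
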