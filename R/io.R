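#' Read and write item-parameter tables
#'
#' The on-disk format is a plain table with one row per item: columns
#' `item_id`, `family` (`linear|2pl|3pl|4pl|rh|nrm`), then the
#' family-specific parameter columns `eta`, `xi`, `psi2`, `delta`, `c`, `d`,
#' or per-category `alpha_1..alpha_K` / `gamma_1..gamma_K` for the nominal
#' model. CSV and JSON (array of row objects) are supported, chosen by file
#' extension. Numeric values round-trip at full double precision.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return `read_item_table()`: an `item_set`. `write_item_table()`: the
#'   path, invisibly.
#' @export
read_item_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  items_from_table(df)
}

#' @rdname read_item_table
#' @param df a data.frame in the item-table layout.
#' @export
items_from_table <- function(df) {
  need <- c("item_id", "family")
  if (!all(need %in% names(df))) {
    stop("item table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  num <- function(row, col) {
    if (!col %in% names(df)) return(NULL)
    v <- suppressWarnings(as.numeric(row[[col]]))
    if (is.na(v)) NULL else v
  }
  items <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    fam <- as.character(row$family)
    lab <- as.character(row$item_id)
    ctx <- function(msg) stop("row ", i, " (", lab, "): ", msg, call. = FALSE)
    switch(fam,
      linear = {
        if (is.null(num(row, "xi")) || is.null(num(row, "psi2")))
          ctx("linear items need columns xi and psi2")
        linear_item(eta = num(row, "eta") %||% 0, xi = num(row, "xi"),
                    psi2 = num(row, "psi2"), label = lab)
      },
      `2pl` = ,
      `3pl` = ,
      `4pl` = {
        if (is.null(num(row, "eta")) || is.null(num(row, "xi")))
          ctx("binary items need columns eta and xi")
        item_2pl(num(row, "eta"), num(row, "xi"),
                 c = num(row, "c") %||% 0, d = num(row, "d") %||% 1,
                 label = lab)
      },
      rh = {
        if (is.null(num(row, "eta")) || is.null(num(row, "xi")) ||
            is.null(num(row, "delta")))
          ctx("rh items need columns eta, xi, delta")
        item_rh(num(row, "eta"), num(row, "xi"), num(row, "delta"), label = lab)
      },
      nrm = {
        ac <- sort(grep("^alpha_[0-9]+$", names(df), value = TRUE))
        gc <- sort(grep("^gamma_[0-9]+$", names(df), value = TRUE))
        if (length(ac) < 2L || length(ac) != length(gc))
          ctx("nrm items need matching alpha_1..K and gamma_1..K columns")
        a <- as.numeric(unlist(row[ac[order(as.integer(sub("alpha_", "", ac)))]]))
        g <- as.numeric(unlist(row[gc[order(as.integer(sub("gamma_", "", gc)))]]))
        item_nrm(a, g, label = lab)
      },
      ctx(paste0("unknown family '", fam, "'"))
    )
  })
  item_set(items, labels = as.character(df$item_id))
}

#' @rdname read_item_table
#' @param items an `item_set`.
#' @export
write_item_table <- function(items, path) {
  df <- items_to_table(items)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) {
      ifelse(is.na(x), NA, formatC(x, digits = 17, format = "g"))
    })
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname read_item_table
#' @export
items_to_table <- function(items) {
  stopifnot(inherits(items, "item_set"))
  fam <- item_family(items)
  if (fam == "nrm") {
    K <- items$items[[1L]]$K
    A <- t(vapply(items$items, `[[`, numeric(K), "alpha"))
    G <- t(vapply(items$items, `[[`, numeric(K), "gamma"))
    colnames(A) <- paste0("alpha_", seq_len(K))
    colnames(G) <- paste0("gamma_", seq_len(K))
    return(data.frame(item_id = items$labels, family = "nrm", A, G,
                      stringsAsFactors = FALSE))
  }
  get_or_na <- function(f) vapply(items$items, function(i) i[[f]] %||% NA_real_,
                                  numeric(1))
  df <- data.frame(item_id = items$labels, family = fam,
                   eta = get_or_na("eta"), xi = get_or_na("xi"),
                   stringsAsFactors = FALSE)
  if (fam == "linear") df$psi2 <- get_or_na("psi2")
  if (fam == "rh") df$delta <- get_or_na("delta")
  if (fam %in% c("3pl", "4pl")) { df$c <- get_or_na("c"); df$d <- get_or_na("d") }
  df
}

#' Read and write response matrices
#'
#' Plain CSV, persons in rows, a header row of item ids, `NA` for missing.
#'
#' @param path CSV file path.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  Y <- as.matrix(utils::read.csv(path, check.names = FALSE))
  storage.mode(Y) <- "double"
  Y
}

#' @rdname read_responses
#' @param Y response matrix.
#' @export
write_responses <- function(Y, path) {
  utils::write.csv(as.data.frame(Y), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Serialize curves as tidy long-format tables
#'
#' One row per (item, theta) with columns `item_id`, `theta`, `value`,
#' `curve_type` (`irf|deriv1|deriv2|info|ifti|rel|weight|test_info`), so any
#' subset of items can be re-plotted without recomputation.
#'
#' @param items an `item_set`.
#' @param grid a [theta_grid()].
#' @param types which curve types to emit.
#' @return A data.frame in the tidy layout.
#' @export
curve_table <- function(items, grid = theta_grid(),
                        types = c("irf", "deriv1", "deriv2", "info", "ifti",
                                  "rel", "weight", "test_info")) {
  types <- match.arg(types, several.ok = TRUE)
  grid <- as_grid(grid)
  th <- as.numeric(grid)
  fam <- item_family(items)
  ic <- information_curves(items, grid)
  fr <- if ("ifti" %in% types) ifti(ic) else NULL
  out <- list()
  add <- function(label, type, value) {
    out[[length(out) + 1L]] <<- data.frame(item_id = label, theta = th,
                                           value = value, curve_type = type,
                                           stringsAsFactors = FALSE)
  }
  for (v in seq_len(items$V)) {
    it <- items$items[[v]]
    lab <- items$labels[v]
    if (fam == "nrm") {
      # per-category curves get suffixed ids
      if ("irf" %in% types) {
        p <- irf(it, th)
        for (k in seq_len(it$K)) add(paste0(lab, ":cat", k), "irf", p[, k])
      }
      if ("deriv1" %in% types) {
        d <- irf_deriv(it, th, 1L)
        for (k in seq_len(it$K)) add(paste0(lab, ":cat", k), "deriv1", d[, k])
      }
      if ("deriv2" %in% types) {
        d <- irf_deriv(it, th, 2L)
        for (k in seq_len(it$K)) add(paste0(lab, ":cat", k), "deriv2", d[, k])
      }
    } else {
      if ("irf" %in% types) add(lab, "irf", as.numeric(irf(it, th)))
      if ("deriv1" %in% types) add(lab, "deriv1", irf_deriv(it, th, 1L))
      if ("deriv2" %in% types) add(lab, "deriv2", irf_deriv(it, th, 2L))
      if ("weight" %in% types && fam != "linear")
        add(lab, "weight", optimal_weights(it, grid))
    }
    if ("info" %in% types) add(lab, "info", ic$info[, v])
    if ("rel" %in% types) add(lab, "rel", reliability(ic$info[, v]))
    if ("ifti" %in% types) add(lab, "ifti", fr$ifti[, v])
  }
  if ("test_info" %in% types) add("TEST", "test_info", test_information(ic))
  do.call(rbind, out)
}

#' @rdname curve_table
#' @param tab a curve table.
#' @param path output CSV path.
#' @export
write_curves <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
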