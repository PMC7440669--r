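# Linear-programming backend: thin wrapper around the GLPK command-line
# solver (glpsol).  Problems are written in CPLEX LP format with sanitised
# variable names and read back from GLPK's plain-text solution file.

glpsol_path <- function() {
  p <- Sys.which("glpsol")
  if (!nzchar(p)) stop("glpsol (GLPK) not found on PATH; it is required for LP solving")
  p
}

# default solver settings recorded in every optimisation result
lp_solver_info <- function() {
  list(backend = "glpsol", feasibility_tol = 1e-9, optimality_tol = 1e-9)
}

#' Solve a linear program over a stoichiometric network (internal)
#'
#' Maximises or minimises `objective %*% v` subject to `S v = 0`, the flux
#' bounds, and optional extra linear rows.
#'
#' @param S sparse constraint matrix (rows are equality constraints = 0).
#' @param lb,ub variable bounds.
#' @param objective named or plain numeric objective coefficients.
#' @param sense `"max"` or `"min"`.
#' @param extra list of extra rows, each `list(coef=, dir=, rhs=)` with
#'   `coef` a numeric vector over all variables and `dir` one of
#'   `">="`, `"<="`, `"="`.
#' @return list with `status` (`"optimal"`/`"infeasible"`/...), `objective`,
#'   and `primal` (named by column names of `S`).
#' @keywords internal
solve_lp <- function(S, lb, ub, objective, sense = "max", extra = list()) {
  n <- ncol(S)
  vn <- paste0("x", seq_len(n))
  Tm <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
  lines <- character(0)
  obj_terms <- which(objective != 0)
  obj_str <- if (length(obj_terms) == 0) "0 x1" else
    paste(sprintf("%+.12g %s", objective[obj_terms], vn[obj_terms]), collapse = " ")
  lines <- c(lines, if (sense == "max") "Maximize" else "Minimize",
             paste(" obj:", obj_str), "Subject To")
  # equality rows S v = 0, grouped by row index
  ord <- order(Tm@i)
  ri <- Tm@i[ord]; ci <- Tm@j[ord]; xv <- Tm@x[ord]
  if (length(ri) > 0) {
    terms <- sprintf("%+.12g %s", xv, vn[ci + 1])
    grp <- split(terms, ri)
    rows <- vapply(names(grp), function(k) {
      sprintf(" m%s: %s = 0", k, paste(grp[[k]], collapse = " "))
    }, character(1))
    lines <- c(lines, rows)
  }
  for (k in seq_along(extra)) {
    e <- extra[[k]]
    nz <- which(e$coef != 0)
    lines <- c(lines, sprintf(" e%d: %s %s %.12g", k,
                              paste(sprintf("%+.12g %s", e$coef[nz], vn[nz]), collapse = " "),
                              if (e$dir == "=") "=" else e$dir, e$rhs))
  }
  lines <- c(lines, "Bounds",
             sprintf(" %.12g <= %s <= %.12g", lb, vn, ub), "End")
  lpf <- tempfile(fileext = ".lp"); solf <- tempfile(fileext = ".sol")
  on.exit(unlink(c(lpf, solf)), add = TRUE)
  writeLines(lines, lpf)
  out <- suppressWarnings(system2(glpsol_path(), c("--lp", shQuote(lpf), "-w", shQuote(solf)),
                                  stdout = TRUE, stderr = TRUE))
  if (!file.exists(solf)) {
    stop("glpsol failed: ", paste(utils::tail(out, 3), collapse = " | "))
  }
  sol <- readLines(solf)
  status_line <- grep("^c Status:", sol, value = TRUE)
  status <- if (length(status_line) > 0) {
    tolower(trimws(sub("^c Status:", "", status_line[1])))
  } else "unknown"
  if (!grepl("optimal", status)) {
    # glpsol reports a primal-infeasible final basis as UNDEFINED
    mapped <- if (grepl("unbounded", status)) "unbounded" else "infeasible"
    return(list(status = mapped, objective = NA_real_, primal = NULL))
  }
  hdr <- strsplit(grep("^s ", sol, value = TRUE)[1], "\\s+")[[1]]
  objval <- as.numeric(hdr[length(hdr)])
  jl <- grep("^j ", sol, value = TRUE)
  jt <- strsplit(jl, "\\s+")
  idx <- vapply(jt, function(t) as.integer(t[2]), integer(1))
  val <- vapply(jt, function(t) as.numeric(t[4]), numeric(1))
  primal <- numeric(n)
  primal[idx] <- val
  names(primal) <- colnames(S)
  list(status = "optimal", objective = objval, primal = primal)
}
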