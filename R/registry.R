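## Registry of the thirteen ODE system variants.
##
## The baseline network (sys1) couples the four hormones through positive
## feedforward (TRH->TSH, TSH->FT4, TSH.FT4->FT3) and negative feedback
## (FT4.FT3 -| TRH, FT4.FT3 -| TSH, modelled as 1/(FT4*FT3) in the
## strong-inhibition regime where the hormone level is far above its
## Michaelis-Menten constant).  Every other variant modifies exactly the
## term(s) named in its description.  State order: TRH, TSH, FT4, FT3.

new_variant <- function(id, description, required, default_extras = numeric(0),
                        rhs, jac, analytic_ft3 = NULL, polynomial_ft3 = NULL,
                        reconstruct = NULL) {
  structure(
    list(id = id, description = description, required = required,
         default_extras = default_extras, rhs = rhs, jac = jac,
         analytic_ft3 = analytic_ft3, polynomial_ft3 = polynomial_ft3,
         reconstruct = reconstruct),
    class = "hpt_system")
}

SYS1_REQUIRED <- c("s1", "a1", "a2", "a3", "a4",
                   "k134", "k21", "c2", "k234", "k32", "k423")

## Closed-form FT3 for the baseline topology (shared by sys1 and sys12,
## where the central drive s1 is modulated by ptTSH).  Manifestly
## independent of k32 and a3: perfect homeostasis.
baseline_ft3 <- function(p, drive) {
  sqrt(p[["k423"]] * (p[["a1"]] * p[["c2"]] * p[["k134"]] +
                        drive * p[["k21"]] * p[["k234"]]) /
         (p[["a1"]] * p[["a2"]] * p[["a4"]] * p[["k134"]] * p[["k234"]]))
}

## Require every constant read by a printed polynomial solution to sit at
## the unit baseline, except the ones the printed form leaves free.
check_poly_validity <- function(p, variant, free) {
  fixed <- setdiff(variant$required, free)
  off <- fixed[abs(p[fixed] - 1) > 1e-9]
  if (length(off)) {
    stop_hpt("the printed polynomial solution for ", variant$id,
             " is only valid with ", paste(fixed, collapse = ", "),
             " fixed at 1 (offending: ", paste(off, collapse = ", "),
             "); use hpt_equilibrium() for general parameters",
             class = "hpt_poly_validity_error")
  }
  invisible(TRUE)
}

make_registry <- function() {
  reg <- list()

  ## -- sys1: full feedforward/feedback network ------------------------------
  reg$sys1 <- new_variant(
    "sys1",
    "Baseline network: FT4.FT3 feedback onto both TRH and TSH (additive TSH production)",
    SYS1_REQUIRED,
    rhs = function(x, p) {
      c(p[["s1"]] / (p[["k134"]] * x[3] * x[4]) - p[["a1"]] * x[1],
        p[["k21"]] * x[1] + p[["c2"]] / (p[["k234"]] * x[3] * x[4]) - p[["a2"]] * x[2],
        p[["k32"]] * x[2] - p[["a3"]] * x[3],
        p[["k423"]] * x[2] * x[3] - p[["a4"]] * x[4])
    },
    jac = function(x, p) {
      matrix(c(
        -p[["a1"]], 0, -p[["s1"]] / (p[["k134"]] * x[3]^2 * x[4]),
        -p[["s1"]] / (p[["k134"]] * x[3] * x[4]^2),
        p[["k21"]], -p[["a2"]], -p[["c2"]] / (p[["k234"]] * x[3]^2 * x[4]),
        -p[["c2"]] / (p[["k234"]] * x[3] * x[4]^2),
        0, p[["k32"]], -p[["a3"]], 0,
        0, p[["k423"]] * x[3], p[["k423"]] * x[2], -p[["a4"]]
      ), nrow = 4, byrow = TRUE, dimnames = list(NULL, HPT_HORMONES))
    },
    analytic_ft3 = function(p) baseline_ft3(p, p[["s1"]])
  )

  ## -- sys1mod: multiplicative coupling of the TSH production terms ---------
  reg$sys1mod <- new_variant(
    "sys1mod",
    "Baseline with multiplicative (serial) coupling of TRH feedforward and thyroid-hormone feedback in TSH production",
    SYS1_REQUIRED,
    rhs = function(x, p) {
      c(p[["s1"]] / (p[["k134"]] * x[3] * x[4]) - p[["a1"]] * x[1],
        p[["k21"]] * x[1] * p[["c2"]] / (p[["k234"]] * x[3] * x[4]) - p[["a2"]] * x[2],
        p[["k32"]] * x[2] - p[["a3"]] * x[3],
        p[["k423"]] * x[2] * x[3] - p[["a4"]] * x[4])
    },
    jac = function(x, p) {
      g <- p[["k21"]] * p[["c2"]] / p[["k234"]]
      matrix(c(
        -p[["a1"]], 0, -p[["s1"]] / (p[["k134"]] * x[3]^2 * x[4]),
        -p[["s1"]] / (p[["k134"]] * x[3] * x[4]^2),
        g / (x[3] * x[4]), -p[["a2"]], -g * x[1] / (x[3]^2 * x[4]),
        -g * x[1] / (x[3] * x[4]^2),
        0, p[["k32"]], -p[["a3"]], 0,
        0, p[["k423"]] * x[3], p[["k423"]] * x[2], -p[["a4"]]
      ), nrow = 4, byrow = TRUE, dimnames = list(NULL, HPT_HORMONES))
    },
    analytic_ft3 = function(p) {
      b <- p[["k32"]] / p[["a3"]]
      A <- p[["k21"]] * p[["c2"]] * p[["s1"]] /
        (p[["a1"]] * p[["a2"]] * p[["k134"]] * p[["k234"]])
      (p[["k423"]]^3 * A^2 / (p[["a4"]]^3 * b))^(1 / 7)
    }
  )

  ## -- sys2: feedback of both FT4 and FT3 onto TRH removed ------------------
  reg$sys2 <- new_variant(
    "sys2",
    "Thyroid-hormone feedback onto TRH clamped: TRH driven by s1 alone",
    setdiff(SYS1_REQUIRED, "k134"),
    rhs = function(x, p) {
      c(p[["s1"]] - p[["a1"]] * x[1],
        p[["k21"]] * x[1] + p[["c2"]] / (p[["k234"]] * x[3] * x[4]) - p[["a2"]] * x[2],
        p[["k32"]] * x[2] - p[["a3"]] * x[3],
        p[["k423"]] * x[2] * x[3] - p[["a4"]] * x[4])
    },
    jac = function(x, p) {
      matrix(c(
        -p[["a1"]], 0, 0, 0,
        p[["k21"]], -p[["a2"]], -p[["c2"]] / (p[["k234"]] * x[3]^2 * x[4]),
        -p[["c2"]] / (p[["k234"]] * x[3] * x[4]^2),
        0, p[["k32"]], -p[["a3"]], 0,
        0, p[["k423"]] * x[3], p[["k423"]] * x[2], -p[["a4"]]
      ), nrow = 4, byrow = TRUE, dimnames = list(NULL, HPT_HORMONES))
    },
    polynomial_ft3 = function(p) {
      v <- reg$sys2; check_poly_validity(p, v, c("k32", "a3"))
      r <- p[["k32"]] / p[["a3"]]
      c(1, 0, -2, -r, 1)                 # ascending: 1 - 2 z^2 - r z^3 + z^4
    },
    reconstruct = function(z, p) {
      r <- p[["k32"]] / p[["a3"]]
      TSH <- sqrt(z / r)
      c(TRH = p[["s1"]] / p[["a1"]], TSH = TSH, FT4 = r * TSH, FT3 = z)
    }
  )

  ## -- sys3: feedback of FT4 and FT3 onto TSH clamped at constants ----------
  reg$sys3 <- new_variant(
    "sys3",
    "Thyroid-hormone feedback onto TSH clamped at FT4_const, FT3_const (constitutive TSH secretion)",
    c(SYS1_REQUIRED, "FT3_const", "FT4_const"),
    rhs = function(x, p) {
      c(p[["s1"]] / (p[["k134"]] * x[3] * x[4]) - p[["a1"]] * x[1],
        p[["k21"]] * x[1] +
          p[["c2"]] / (p[["k234"]] * p[["FT4_const"]] * p[["FT3_const"]]) -
          p[["a2"]] * x[2],
        p[["k32"]] * x[2] - p[["a3"]] * x[3],
        p[["k423"]] * x[2] * x[3] - p[["a4"]] * x[4])
    },
    jac = function(x, p) {
      matrix(c(
        -p[["a1"]], 0, -p[["s1"]] / (p[["k134"]] * x[3]^2 * x[4]),
        -p[["s1"]] / (p[["k134"]] * x[3] * x[4]^2),
        p[["k21"]], -p[["a2"]], 0, 0,
        0, p[["k32"]], -p[["a3"]], 0,
        0, p[["k423"]] * x[3], p[["k423"]] * x[2], -p[["a4"]]
      ), nrow = 4, byrow = TRUE, dimnames = list(NULL, HPT_HORMONES))
    },
    polynomial_ft3 = function(p) {
      v <- reg$sys3
      check_poly_validity(p, v, c("k32", "a3", "FT3_const", "FT4_const"))
      r <- p[["k32"]] / (p[["a3"]] * p[["FT3_const"]]^2 * p[["FT4_const"]]^2)
      c(1, 0, -2, -r, 1)
    },
    reconstruct = function(z, p) {
      r <- p[["k32"]] / p[["a3"]]
      TSH <- sqrt(z / r)
      c(TRH = 1 / (r * TSH * z), TSH = TSH, FT4 = r * TSH, FT3 = z)
    }
  )

  ## -- sys4: FT3 feedback onto TRH clamped, FT4 influence free --------------
  reg$sys4 <- new_variant(
    "sys4",
    "FT3 feedback onto TRH clamped at FT3_const; FT4 feedback onto TRH intact",
    c(setdiff(SYS1_REQUIRED, "k134"), "k13", "FT3_const"),
    rhs = function(x, p) {
      c(p[["s1"]] / (p[["k13"]] * p[["FT3_const"]] * x[3]) - p[["a1"]] * x[1],
        p[["k21"]] * x[1] + p[["c2"]] / (p[["k234"]] * x[3] * x[4]) - p[["a2"]] * x[2],
        p[["k32"]] * x[2] - p[["a3"]] * x[3],
        p[["k423"]] * x[2] * x[3] - p[["a4"]] * x[4])
    },
    jac = function(x, p) {
      matrix(c(
        -p[["a1"]], 0, -p[["s1"]] / (p[["k13"]] * p[["FT3_const"]] * x[3]^2), 0,
        p[["k21"]], -p[["a2"]], -p[["c2"]] / (p[["k234"]] * x[3]^2 * x[4]),
        -p[["c2"]] / (p[["k234"]] * x[3] * x[4]^2),
        0, p[["k32"]], -p[["a3"]], 0,
        0, p[["k423"]] * x[3], p[["k423"]] * x[2], -p[["a4"]]
      ), nrow = 4, byrow = TRUE, dimnames = list(NULL, HPT_HORMONES))
    },
    ## Positive root of the quadratic in v = (k32/a3) * TSH^2; k32 and a3
    ## cancel out of FT3 = k423*v/a4 (perfect homeostasis at a shifted level).
    analytic_ft3 = function(p) {
      B <- p[["k21"]] * p[["s1"]] / (p[["a1"]] * p[["k13"]] * p[["FT3_const"]])
      C <- p[["c2"]] * p[["a4"]] / (p[["k234"]] * p[["k423"]])
      v <- (B + sqrt(B^2 + 4 * p[["a2"]] * C)) / (2 * p[["a2"]])
      p[["k423"]] * v / p[["a4"]]
    }
  )

  ## -- sys5: FT4 feedback onto TRH clamped, FT3 influence free --------------
  reg$sys5 <- new_variant(
    "sys5",
    "FT4 feedback onto TRH clamped; only FT3 feeds back onto TRH",
    c(setdiff(SYS1_REQUIRED, "k134"), "k14"),
    rhs = function(x, p) {
      c(p[["s1"]] / (p[["k14"]] * x[4]) - p[["a1"]] * x[1],
        p[["k21"]] * x[1] + p[["c2"]] / (p[["k234"]] * x[3] * x[4]) - p[["a2"]] * x[2],
        p[["k32"]] * x[2] - p[["a3"]] * x[3],
        p[["k423"]] * x[2] * x[3] - p[["a4"]] * x[4])
    },
    jac = function(x, p) {
      matrix(c(
        -p[["a1"]], 0, 0, -p[["s1"]] / (p[["k14"]] * x[4]^2),
        p[["k21"]], -p[["a2"]], -p[["c2"]] / (p[["k234"]] * x[3]^2 * x[4]),
        -p[["c2"]] / (p[["k234"]] * x[3] * x[4]^2),
        0, p[["k32"]], -p[["a3"]], 0,
        0, p[["k423"]] * x[3], p[["k423"]] * x[2], -p[["a4"]]
      ), nrow = 4, byrow = TRUE, dimnames = list(NULL, HPT_HORMONES))
    },
    polynomial_ft3 = function(p) {
      v <- reg$sys5; check_poly_validity(p, v, c("k32", "a3"))
      a3 <- p[["a3"]]
      c(a3, -p[["k32"]], -2 * a3, 0, a3)  # a3 - k32 z - 2 a3 z^2 + a3 z^4
    },
    reconstruct = function(z, p) {
      r <- p[["k32"]] / p[["a3"]]
      TSH <- sqrt(z / r)
      c(TRH = 1 / z, TSH = TSH, FT4 = r * TSH, FT3 = z)
    }
  )

  ## -- sys6: FT3 feedback onto TSH clamped, FT4 influence free --------------
  reg$sys6 <- new_variant(
    "sys6",
    "FT3 feedback onto TSH clamped at FT3_const; FT4 feedback onto TSH intact",
    c(setdiff(SYS1_REQUIRED, "k234"), "k23", "FT3_const"),
    rhs = function(x, p) {
      c(p[["s1"]] / (p[["k134"]] * x[3] * x[4]) - p[["a1"]] * x[1],
        p[["k21"]] * x[1] + p[["c2"]] / (p[["k23"]] * p[["FT3_const"]] * x[3]) -
          p[["a2"]] * x[2],
        p[["k32"]] * x[2] - p[["a3"]] * x[3],
        p[["k423"]] * x[2] * x[3] - p[["a4"]] * x[4])
    },
    jac = function(x, p) {
      matrix(c(
        -p[["a1"]], 0, -p[["s1"]] / (p[["k134"]] * x[3]^2 * x[4]),
        -p[["s1"]] / (p[["k134"]] * x[3] * x[4]^2),
        p[["k21"]], -p[["a2"]],
        -p[["c2"]] / (p[["k23"]] * p[["FT3_const"]] * x[3]^2), 0,
        0, p[["k32"]], -p[["a3"]], 0,
        0, p[["k423"]] * x[3], p[["k423"]] * x[2], -p[["a4"]]
      ), nrow = 4, byrow = TRUE, dimnames = list(NULL, HPT_HORMONES))
    },
    analytic_ft3 = function(p) {
      C <- p[["c2"]] / (p[["k23"]] * p[["FT3_const"]])
      K <- p[["k21"]] * p[["s1"]] * p[["a4"]] /
        (p[["a1"]] * p[["k134"]] * p[["k423"]])
      v <- (C + sqrt(C^2 + 4 * p[["a2"]] * K)) / (2 * p[["a2"]])
      p[["k423"]] * v / p[["a4"]]
    }
  )

  ## -- sys7: FT4 feedback onto TSH clamped, FT3 influence free --------------
  reg$sys7 <- new_variant(
    "sys7",
    "FT4 feedback onto TSH clamped; only FT3 feeds back onto TSH",
    c(setdiff(SYS1_REQUIRED, "k234"), "k24"),
    rhs = function(x, p) {
      c(p[["s1"]] / (p[["k134"]] * x[3] * x[4]) - p[["a1"]] * x[1],
        p[["k21"]] * x[1] + p[["c2"]] / (p[["k24"]] * x[4]) - p[["a2"]] * x[2],
        p[["k32"]] * x[2] - p[["a3"]] * x[3],
        p[["k423"]] * x[2] * x[3] - p[["a4"]] * x[4])
    },
    jac = function(x, p) {
      matrix(c(
        -p[["a1"]], 0, -p[["s1"]] / (p[["k134"]] * x[3]^2 * x[4]),
        -p[["s1"]] / (p[["k134"]] * x[3] * x[4]^2),
        p[["k21"]], -p[["a2"]], 0, -p[["c2"]] / (p[["k24"]] * x[4]^2),
        0, p[["k32"]], -p[["a3"]], 0,
        0, p[["k423"]] * x[3], p[["k423"]] * x[2], -p[["a4"]]
      ), nrow = 4, byrow = TRUE, dimnames = list(NULL, HPT_HORMONES))
    },
    polynomial_ft3 = function(p) {
      v <- reg$sys7; check_poly_validity(p, v, c("k32", "a3"))
      r <- p[["k32"]] / p[["a3"]]
      c(1, -r, -2, 0, 1)                 # 1 - r z - 2 z^2 + z^4
    },
    reconstruct = function(z, p) {
      r <- p[["k32"]] / p[["a3"]]
      TSH <- sqrt(z / r)
      c(TRH = 1 / (r * TSH * z), TSH = TSH, FT4 = r * TSH, FT3 = z)
    }
  )

  ## -- sys8: TSH feedforward onto FT3 removed; conversion from FT4 only -----
  reg$sys8 <- new_variant(
    "sys8",
    "No TSH.FT4 feedforward onto FT3; FT3 produced from FT4 alone (k43)",
    c(setdiff(SYS1_REQUIRED, "k423"), "k43"),
    default_extras = c(k43 = 1),
    rhs = function(x, p) {
      c(p[["s1"]] / (p[["k134"]] * x[3] * x[4]) - p[["a1"]] * x[1],
        p[["k21"]] * x[1] + p[["c2"]] / (p[["k234"]] * x[3] * x[4]) - p[["a2"]] * x[2],
        p[["k32"]] * x[2] - p[["a3"]] * x[3],
        p[["k43"]] * x[3] - p[["a4"]] * x[4])
    },
    jac = function(x, p) {
      matrix(c(
        -p[["a1"]], 0, -p[["s1"]] / (p[["k134"]] * x[3]^2 * x[4]),
        -p[["s1"]] / (p[["k134"]] * x[3] * x[4]^2),
        p[["k21"]], -p[["a2"]], -p[["c2"]] / (p[["k234"]] * x[3]^2 * x[4]),
        -p[["c2"]] / (p[["k234"]] * x[3] * x[4]^2),
        0, p[["k32"]], -p[["a3"]], 0,
        0, 0, p[["k43"]], -p[["a4"]]
      ), nrow = 4, byrow = TRUE, dimnames = list(NULL, HPT_HORMONES))
    },
    analytic_ft3 = function(p) {
      E <- (p[["k21"]] * p[["s1"]] / (p[["a1"]] * p[["k134"]]) +
              p[["c2"]] / p[["k234"]]) / p[["a2"]]
      (p[["k43"]]^2 * (p[["k32"]] / p[["a3"]]) * E / p[["a4"]]^2)^(1 / 3)
    }
  )

  ## -- sys9: baseline plus peripheral (TSH-independent) T4->T3 conversion ---
  reg$sys9 <- new_variant(
    "sys9",
    "Baseline plus peripheral deiodinase FT3 production k43*FT4",
    c(SYS1_REQUIRED, "k43"),
    default_extras = c(k43 = 1),
    rhs = function(x, p) {
      c(p[["s1"]] / (p[["k134"]] * x[3] * x[4]) - p[["a1"]] * x[1],
        p[["k21"]] * x[1] + p[["c2"]] / (p[["k234"]] * x[3] * x[4]) - p[["a2"]] * x[2],
        p[["k32"]] * x[2] - p[["a3"]] * x[3],
        p[["k423"]] * x[2] * x[3] + p[["k43"]] * x[3] - p[["a4"]] * x[4])
    },
    jac = function(x, p) {
      matrix(c(
        -p[["a1"]], 0, -p[["s1"]] / (p[["k134"]] * x[3]^2 * x[4]),
        -p[["s1"]] / (p[["k134"]] * x[3] * x[4]^2),
        p[["k21"]], -p[["a2"]], -p[["c2"]] / (p[["k234"]] * x[3]^2 * x[4]),
        -p[["c2"]] / (p[["k234"]] * x[3] * x[4]^2),
        0, p[["k32"]], -p[["a3"]], 0,
        0, p[["k423"]] * x[3], p[["k423"]] * x[2] + p[["k43"]], -p[["a4"]]
      ), nrow = 4, byrow = TRUE, dimnames = list(NULL, HPT_HORMONES))
    },
    polynomial_ft3 = function(p) {
      v <- reg$sys9; check_poly_validity(p, v, "a3")
      a3 <- p[["a3"]]
      c(4 * a3, -2, -4 * a3, 0, a3)      # 4 a3 - 2 z - 4 a3 z^2 + a3 z^4
    },
    reconstruct = function(z, p) {
      a3 <- p[["a3"]]
      TSH <- (-1 + sqrt(1 + 4 * a3 * z)) / 2
      F4 <- TSH / a3
      c(TRH = 1 / (F4 * z), TSH = TSH, FT4 = F4, FT3 = z)
    }
  )

  ## -- sys10: sys9 plus de novo thyroidal FT3 secretion ---------------------
  reg$sys10 <- new_variant(
    "sys10",
    "sys9 plus TSH-dependent de novo thyroidal FT3 production k42*TSH",
    c(SYS1_REQUIRED, "k43", "k42"),
    default_extras = c(k43 = 1, k42 = 1),
    rhs = function(x, p) {
      c(p[["s1"]] / (p[["k134"]] * x[3] * x[4]) - p[["a1"]] * x[1],
        p[["k21"]] * x[1] + p[["c2"]] / (p[["k234"]] * x[3] * x[4]) - p[["a2"]] * x[2],
        p[["k32"]] * x[2] - p[["a3"]] * x[3],
        p[["k423"]] * x[2] * x[3] + p[["k43"]] * x[3] + p[["k42"]] * x[2] -
          p[["a4"]] * x[4])
    },
    jac = function(x, p) {
      matrix(c(
        -p[["a1"]], 0, -p[["s1"]] / (p[["k134"]] * x[3]^2 * x[4]),
        -p[["s1"]] / (p[["k134"]] * x[3] * x[4]^2),
        p[["k21"]], -p[["a2"]], -p[["c2"]] / (p[["k234"]] * x[3]^2 * x[4]),
        -p[["c2"]] / (p[["k234"]] * x[3] * x[4]^2),
        0, p[["k32"]], -p[["a3"]], 0,
        0, p[["k423"]] * x[3] + p[["k42"]], p[["k423"]] * x[2] + p[["k43"]],
        -p[["a4"]]
      ), nrow = 4, byrow = TRUE, dimnames = list(NULL, HPT_HORMONES))
    },
    polynomial_ft3 = function(p) {
      v <- reg$sys10; check_poly_validity(p, v, "a3")
      a3 <- p[["a3"]]
      c(4 * a3, -(2 * a3^2 + 4 * a3 + 2), -4 * a3, 0, a3)
    },
    reconstruct = function(z, p) {
      a3 <- p[["a3"]]
      TSH <- (-(1 + a3) + sqrt((1 + a3)^2 + 4 * a3 * z)) / 2
      F4 <- TSH / a3
      c(TRH = 1 / (F4 * z), TSH = TSH, FT4 = F4, FT3 = z)
    }
  )

  ## -- sys11: sys10 plus constant external T3/T4 administration -------------
  reg$sys11 <- new_variant(
    "sys11",
    "sys10 plus constant external FT3 (drug3) and FT4 (drug4) production rates",
    c(SYS1_REQUIRED, "k43", "k42", "drug3", "drug4"),
    default_extras = c(k43 = 1, k42 = 1, drug3 = 0, drug4 = 0),
    rhs = function(x, p) {
      c(p[["s1"]] / (p[["k134"]] * x[3] * x[4]) - p[["a1"]] * x[1],
        p[["k21"]] * x[1] + p[["c2"]] / (p[["k234"]] * x[3] * x[4]) - p[["a2"]] * x[2],
        p[["k32"]] * x[2] + p[["drug4"]] - p[["a3"]] * x[3],
        p[["k423"]] * x[2] * x[3] + p[["k43"]] * x[3] + p[["k42"]] * x[2] +
          p[["drug3"]] - p[["a4"]] * x[4])
    },
    jac = function(x, p) {
      matrix(c(
        -p[["a1"]], 0, -p[["s1"]] / (p[["k134"]] * x[3]^2 * x[4]),
        -p[["s1"]] / (p[["k134"]] * x[3] * x[4]^2),
        p[["k21"]], -p[["a2"]], -p[["c2"]] / (p[["k234"]] * x[3]^2 * x[4]),
        -p[["c2"]] / (p[["k234"]] * x[3] * x[4]^2),
        0, p[["k32"]], -p[["a3"]], 0,
        0, p[["k423"]] * x[3] + p[["k42"]], p[["k423"]] * x[2] + p[["k43"]],
        -p[["a4"]]
      ), nrow = 4, byrow = TRUE, dimnames = list(NULL, HPT_HORMONES))
    }
  )

  ## -- sys12: baseline with seasonally modulated central drive --------------
  reg$sys12 <- new_variant(
    "sys12",
    "Baseline with seasonal modulation ptTSH of the central TRH drive",
    c(SYS1_REQUIRED, "ptTSH"),
    rhs = function(x, p) {
      c(p[["ptTSH"]] * p[["s1"]] / (p[["k134"]] * x[3] * x[4]) - p[["a1"]] * x[1],
        p[["k21"]] * x[1] + p[["c2"]] / (p[["k234"]] * x[3] * x[4]) - p[["a2"]] * x[2],
        p[["k32"]] * x[2] - p[["a3"]] * x[3],
        p[["k423"]] * x[2] * x[3] - p[["a4"]] * x[4])
    },
    jac = function(x, p) {
      d <- p[["ptTSH"]] * p[["s1"]]
      matrix(c(
        -p[["a1"]], 0, -d / (p[["k134"]] * x[3]^2 * x[4]),
        -d / (p[["k134"]] * x[3] * x[4]^2),
        p[["k21"]], -p[["a2"]], -p[["c2"]] / (p[["k234"]] * x[3]^2 * x[4]),
        -p[["c2"]] / (p[["k234"]] * x[3] * x[4]^2),
        0, p[["k32"]], -p[["a3"]], 0,
        0, p[["k423"]] * x[3], p[["k423"]] * x[2], -p[["a4"]]
      ), nrow = 4, byrow = TRUE, dimnames = list(NULL, HPT_HORMONES))
    },
    analytic_ft3 = function(p) baseline_ft3(p, p[["ptTSH"]] * p[["s1"]])
  )

  reg
}

.hpt_registry <- make_registry()

#' List the registered system variants
#'
#' @return a data frame with one row per variant: its identifier, a one
#'   line description, and whether a closed-form or polynomial
#'   equilibrium FT3 solution is available.
#' @examples
#' hpt_systems()
#' @export
hpt_systems <- function() {
  data.frame(
    id = names(.hpt_registry),
    description = vapply(.hpt_registry, `[[`, "", "description"),
    analytic_ft3 = vapply(.hpt_registry,
                          function(v) !is.null(v$analytic_ft3), logical(1)),
    polynomial_ft3 = vapply(.hpt_registry,
                            function(v) !is.null(v$polynomial_ft3), logical(1)),
    row.names = NULL
  )
}

#' Look up a system variant
#'
#' @param id a variant identifier (one of \code{hpt_systems()$id}), or an
#'   already-resolved \code{hpt_system} object (returned unchanged).
#' @return an object of class \code{hpt_system} with the variant's
#'   right-hand side and Jacobian bound.
#' @examples
#' hpt_system("sys1")
#' @export
hpt_system <- function(id) {
  if (inherits(id, "hpt_system")) return(id)
  if (!is.character(id) || length(id) != 1L || is.na(match(id, names(.hpt_registry)))) {
    stop_hpt("unknown system variant ", deparse(id), "; valid ids: ",
             paste(names(.hpt_registry), collapse = ", "),
             class = "hpt_lookup_error")
  }
  .hpt_registry[[id]]
}

#' @export
print.hpt_system <- function(x, ...) {
  cat("<hpt_system> ", x$id, "\n  ", x$description, "\n", sep = "")
  cat("  parameters: ", paste(x$required, collapse = ", "), "\n", sep = "")
  sol <- if (!is.null(x$analytic_ft3)) "closed-form FT3"
  else if (!is.null(x$polynomial_ft3)) "polynomial FT3"
  else "numeric only"
  cat("  equilibrium solution: ", sol, "\n", sep = "")
  invisible(x)
}
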