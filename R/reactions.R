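# The curated poised-reaction knowledge base and its transform engine.
#
# Each reaction couples a product SMARTS (whose atom order is a fixed
# contract) with a retro transform (graph edits on the matched atoms,
# producing synthons with commercial leaving-group conventions) and a forward
# transform (graph edits joining role-matched synthons). Transform bodies are
# keyed by reaction name in .engines; the declarative fields live in the
# ReactionDefinition objects and in the exportable YAML roster.

.engines <- new.env(parent = emptyenv())

# ---- shared SMARTS fragments -------------------------------------------------

# a nucleophilic amine: sp3 neutral N with >=1 H, not amide/thioamide/
# sulfonamide N, not part of N-N or N-O
.AMINE_H <- paste0("[NX3;+0;H1,H2,H3;!$([NX3][CX3]=[OX1]);",
                   "!$([NX3][CX3]=[SX1]);!$([NX3][SX4]);!$([NX3][NX3,NX2,OX2])]")
.ACYL_CL <- "[CX3](=[OX1])[Cl]"

.INCOMPAT <- c(
  free_amine = paste0("[NX3;H1,H2;+0;!$([NX3][CX3]=[OX1]);",
                      "!$([NX3][CX3]=[SX1]);!$([NX3][SX4]);!$([NX3][NX3,NX2])]"),
  acid_halide = "[CX3](=[OX1])[OX2H1,Cl,Br]",
  aldehyde = "[CX3;H1]=[OX1]",
  aryl_halide = "[c][Cl,Br,I]",
  boronic_acid = "[BX3]([OX2;H1])[OX2;H1]",
  phenol_oh = "[c][OX2;H1]",
  alkyl_halide = "[CX4][Cl,Br,I]",
  terminal_alkyne = "[CX2;H1]#[CX2]",
  azide_grp = "[NX2]=[NX2;+1]=[NX1;-1]",
  nitrile_grp = "[CX2]#[NX1]"
)

.INCOMPAT_REASON <- c(
  free_amine = "cross-reactive amine",
  acid_halide = "cross-reactive acid/acyl halide",
  aldehyde = "cross-reactive aldehyde",
  aryl_halide = "cross-reactive aryl halide",
  boronic_acid = "cross-reactive boronic acid",
  phenol_oh = "cross-reactive phenol",
  alkyl_halide = "cross-reactive alkyl halide",
  terminal_alkyne = "cross-reactive terminal alkyne",
  azide_grp = "cross-reactive azide",
  nitrile_grp = "cross-reactive nitrile"
)

.mkdef <- function(name, category, classes, productSmarts, roleSmarts,
                   incompatNames, allowance = NULL, provenance = "") {
  inc <- .INCOMPAT[incompatNames]
  alw <- stats::setNames(integer(length(incompatNames)), incompatNames)
  if (!is.null(allowance)) alw[names(allowance)] <- as.integer(allowance)
  new("ReactionDefinition", name = name, category = category,
      synthonClasses = classes, productSmarts = productSmarts,
      roleSmarts = roleSmarts, incompat = inc, allowance = alw,
      provenance = provenance)
}

# helper: cut one acyclic bond, cap side `capAt` with `cap`, return both halves
.cut2 <- function(mol, i, j, capAtom = NULL, capAt = NULL, capOrder = 1) {
  mol <- .molDelBond(mol, i, j)
  if (!is.null(capAtom)) mol <- .molAddAtom(mol, capAtom, to = capAt,
                                            order = capOrder)$mol
  mol
}

# ---- built-in reaction roster ------------------------------------------------

.builtinDefs <- function() {
  defs <- list()
  eng <- list()

  ## --- linking reactions (8) -------------------------------------------------

  # amide: R-C(=O)-NR'R'' -> R-C(=O)Cl + HNR'R''
  defs$amide <- .mkdef("amide", "linking", c("acyl_chloride", "amine"),
    "[CX3;!$([CX3](=[OX1])([NX3])[!#6;!#1])](=[OX1])!@[NX3;!$([NX3][SX4])]",
    c(.ACYL_CL, .AMINE_H),
    c("free_amine", "acid_halide", "aldehyde"),
    provenance = "amide coupling; most-used medicinal chemistry linkage")
  eng$amide <- list(
    retro = function(mol, map) {
      mol <- .molDelBond(mol, map[1], map[3])
      mol <- .molAddAtom(mol, "Cl", to = map[1])$mol
      list(.molFragment(mol, map[1]), .molFragment(mol, map[3]))
    },
    forward = function(mols, maps) {
      cb <- .molCombine(mols[[1]], mols[[2]])
      m <- .molSetBond(cb$mol, maps[[1]][1], cb$offset + maps[[2]][1], 1)
      .molDelAtoms(m, maps[[1]][3])
    })

  # sulfonamide: R-SO2-NR' -> R-SO2Cl + amine
  defs$sulfonamide <- .mkdef("sulfonamide", "linking",
    c("sulfonyl_chloride", "amine"),
    "[SX4;$([SX4][#6])](=[OX1])(=[OX1])!@[NX3]",
    c("[SX4](=[OX1])(=[OX1])[Cl]", .AMINE_H),
    c("free_amine", "acid_halide", "aldehyde"),
    provenance = "sulfonamide formation from sulfonyl chloride")
  eng$sulfonamide <- list(
    retro = function(mol, map) {
      mol <- .molDelBond(mol, map[1], map[4])
      mol <- .molAddAtom(mol, "Cl", to = map[1])$mol
      list(.molFragment(mol, map[1]), .molFragment(mol, map[4]))
    },
    forward = function(mols, maps) {
      cb <- .molCombine(mols[[1]], mols[[2]])
      m <- .molSetBond(cb$mol, maps[[1]][1], cb$offset + maps[[2]][1], 1)
      .molDelAtoms(m, maps[[1]][4])
    })

  # reductive amination: amine-CH< -> amine + carbonyl
  defs$reductive_amination <- .mkdef("reductive_amination", "linking",
    c("amine", "carbonyl"),
    paste0("[NX3;+0;!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[SX1]);!$([NX3][SX4]);",
           "!$([NX3][OX2]);!$([NX3][NX3,NX2])]!@",
           "[CX4;H1,H2,H3;!$([CX4][OX2]);!$([CX4][SX2]);!$([CX4][F,Cl,Br,I])]"),
    c(.AMINE_H, "[CX3;!$([CX3](=[OX1])[!#6;!#1])](=[OX1])"),
    c("acid_halide", "aldehyde", "free_amine"),
    allowance = c(free_amine = 1L),
    provenance = "reductive amination of an aldehyde/ketone")
  eng$reductive_amination <- list(
    retro = function(mol, map) {
      mol <- .molDelBond(mol, map[1], map[2])
      mol <- .molAddAtom(mol, "O", to = map[2], order = 2)$mol
      list(.molFragment(mol, map[1]), .molFragment(mol, map[2]))
    },
    forward = function(mols, maps) {
      cb <- .molCombine(mols[[1]], mols[[2]])
      m <- .molSetBond(cb$mol, maps[[1]][1], cb$offset + maps[[2]][1], 1)
      .molDelAtoms(m, cb$offset + maps[[2]][2])
    })

  # Suzuki biaryl coupling: Ar-Ar' -> Ar-B(OH)2 + Ar'-Br
  defs$suzuki <- .mkdef("suzuki", "linking",
    c("aryl_boronic_acid", "aryl_halide"),
    "[cX3]!@[cX3]",
    c("[cX3][BX3]([OX2;H1])[OX2;H1]", "[cX3][Br,I]"),
    c("aryl_halide", "boronic_acid"),
    provenance = "Suzuki-Miyaura aryl-aryl cross-coupling")
  eng$suzuki <- list(
    retro = function(mol, map) {
      mol <- .molDelBond(mol, map[1], map[2])
      r <- .molAddAtom(mol, "B", to = map[1]); mol <- r$mol; b <- r$idx
      mol <- .molAddAtom(mol, "O", to = b)$mol
      mol <- .molAddAtom(mol, "O", to = b)$mol
      mol <- .molAddAtom(mol, "Br", to = map[2])$mol
      list(.molFragment(mol, map[1]), .molFragment(mol, map[2]))
    },
    forward = function(mols, maps) {
      cb <- .molCombine(mols[[1]], mols[[2]])
      m <- .molSetBond(cb$mol, maps[[1]][1], cb$offset + maps[[2]][1], 1)
      .molDelAtoms(m, c(maps[[1]][2:4], cb$offset + maps[[2]][2]))
    })

  # Sonogashira: Ar-C#C-R -> Ar-Br + HC#C-R
  defs$sonogashira <- .mkdef("sonogashira", "linking",
    c("aryl_halide", "alkyne"),
    "[cX3]!@[CX2]#[CX2]",
    c("[cX3][Br,I]", "[CX2;H1]#[CX2]"),
    c("aryl_halide", "terminal_alkyne"),
    allowance = c(terminal_alkyne = 0L),
    provenance = "Sonogashira aryl-alkyne coupling")
  eng$sonogashira <- list(
    retro = function(mol, map) {
      mol <- .molDelBond(mol, map[1], map[2])
      mol <- .molAddAtom(mol, "Br", to = map[1])$mol
      list(.molFragment(mol, map[1]), .molFragment(mol, map[2]))
    },
    forward = function(mols, maps) {
      cb <- .molCombine(mols[[1]], mols[[2]])
      m <- .molSetBond(cb$mol, maps[[1]][1], cb$offset + maps[[2]][1], 1)
      .molDelAtoms(m, maps[[1]][2])
    })

  # Williamson aryl ether: Ar-O-CH2R/CH3 -> Ar-OH + R-CH2-Br
  defs$ether <- .mkdef("ether", "linking",
    c("phenol", "alkyl_halide"),
    "[cX3][OX2;R0;!$([OX2][CX3]=[OX1])]!@[CX4;H3,$([CX4;H2]([OX2])[#6])]",
    c("[cX3][OX2;H1]", "[CX4;H2,H3][Br,Cl,I]"),
    c("phenol_oh", "alkyl_halide"),
    provenance = "Williamson O-alkylation of a phenol")
  eng$ether <- list(
    retro = function(mol, map) {
      mol <- .molDelBond(mol, map[2], map[3])
      mol <- .molAddAtom(mol, "Br", to = map[3])$mol
      list(.molFragment(mol, map[2]), .molFragment(mol, map[3]))
    },
    forward = function(mols, maps) {
      cb <- .molCombine(mols[[1]], mols[[2]])
      m <- .molSetBond(cb$mol, maps[[1]][2], cb$offset + maps[[2]][1], 1)
      .molDelAtoms(m, cb$offset + maps[[2]][2])
    })

  # SNAr amination: (azine)Ar-NR2 -> (azine)Ar-Cl + amine
  .cAct <- "[cX3;$(c:[nX2]),$(c:a:[nX2]),$(c:a:a:[nX2])]"
  defs$snar_amination <- .mkdef("snar_amination", "linking",
    c("heteroaryl_halide", "amine"),
    paste0(.cAct, "!@[NX3;+0;!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[SX1]);",
           "!$([NX3][SX4]);!$([NX3][NX3,NX2,OX2])]"),
    c(paste0(.cAct, "[F,Cl,Br]"), .AMINE_H),
    c("acid_halide", "aldehyde", "free_amine"),
    allowance = c(free_amine = 1L),
    provenance = "nucleophilic aromatic substitution on an azine")
  eng$snar_amination <- list(
    retro = function(mol, map) {
      mol <- .molDelBond(mol, map[1], map[2])
      mol <- .molAddAtom(mol, "Cl", to = map[1])$mol
      list(.molFragment(mol, map[1]), .molFragment(mol, map[2]))
    },
    forward = function(mols, maps) {
      cb <- .molCombine(mols[[1]], mols[[2]])
      m <- .molSetBond(cb$mol, maps[[1]][1], cb$offset + maps[[2]][1], 1)
      .molDelAtoms(m, maps[[1]][2])
    })

  # (thio)urea from two amines via thiocarbonyldiimidazole
  defs$thiourea <- .mkdef("thiourea", "linking", c("amine", "amine"),
    "[NX3;+0]!@[CX3](=[SX1])!@[NX3;+0]",
    c(.AMINE_H, .AMINE_H),
    c("free_amine", "acid_halide", "aldehyde"),
    provenance = "sequential amine addition to thio-CDI")
  eng$thiourea <- list(
    retro = function(mol, map) {
      mol <- .molDelBond(mol, map[1], map[2])
      mol <- .molDelBond(mol, map[2], map[4])
      f1 <- .molFragment(mol, map[1])
      f2 <- .molFragment(mol, map[4])
      if (nrow(f2$atoms) > nrow(f1$atoms)) list(f2, f1) else list(f1, f2)
    },
    forward = function(mols, maps) {
      cb <- .molCombine(mols[[1]], mols[[2]])
      r <- .molAddAtom(cb$mol, "C", to = maps[[1]][1]); m <- r$mol; cc <- r$idx
      m <- .molAddAtom(m, "S", to = cc, order = 2)$mol
      .molSetBond(m, cc, cb$offset + maps[[2]][1], 1)
    })

  ## --- heterocycle-forming reactions (13) ------------------------------------

  # benzimidazole: 2-R-benzimidazole -> R-COCl + benzene-1,2-diamine
  defs$benzimidazole <- .mkdef("benzimidazole", "heterocycle",
    c("acyl_chloride", "aryl_diamine"),
    "[cX3;R2]1[cX3;R2][nX3;H1,$([nX3][#6])][cX3][nX2]1",
    c(.ACYL_CL, "[NX3;H1,H2]!@[cX3]:[cX3]!@[NX3;H2]"),
    c("free_amine", "acid_halide", "aldehyde"),
    provenance = "benzimidazole condensation (heterocycle set)")
  .benzofusedRetro <- function(mol, map) {
    # map: c3a, c7a, X1(N/O/S), C2, N3
    mol <- .molDelBond(mol, map[3], map[4])
    mol <- .molDelBond(mol, map[4], map[5])
    mol <- .molAddAtom(mol, "O", to = map[4], order = 2)$mol
    mol <- .molAddAtom(mol, "Cl", to = map[4])$mol
    list(.molFragment(mol, map[4]), .molFragment(mol, map[3]))
  }
  .benzofusedForward <- function(mols, maps) {
    # A: acyl (C,O,Cl); B: X-c:c-N (X = NH/OH/SH, then the NH2)
    cb <- .molCombine(mols[[1]], mols[[2]])
    m <- .molSetBond(cb$mol, maps[[1]][1], cb$offset + maps[[2]][1], 1)
    m <- .molSetBond(m, maps[[1]][1], cb$offset + maps[[2]][4], 2)
    .molDelAtoms(m, maps[[1]][2:3])
  }
  eng$benzimidazole <- list(retro = .benzofusedRetro, forward = .benzofusedForward)

  # benzoxazole: 2-R-benzoxazole -> R-COCl + 2-aminophenol
  defs$benzoxazole <- .mkdef("benzoxazole", "heterocycle",
    c("acyl_chloride", "aminophenol"),
    "[cX3;R2]1[cX3;R2][oX2][cX3][nX2]1",
    c(.ACYL_CL, "[OX2;H1]!@[cX3]:[cX3]!@[NX3;H2]"),
    c("free_amine", "acid_halide", "aldehyde"),
    provenance = "benzoxazole condensation (heterocycle set)")
  eng$benzoxazole <- list(
    retro = .benzofusedRetro,
    forward = function(mols, maps) {
      # ring O comes from the phenol; C2=N3 to the aniline nitrogen
      cb <- .molCombine(mols[[1]], mols[[2]])
      m <- .molSetBond(cb$mol, maps[[1]][1], cb$offset + maps[[2]][1], 1)
      m <- .molSetBond(m, maps[[1]][1], cb$offset + maps[[2]][4], 2)
      .molDelAtoms(m, maps[[1]][2:3])
    })

  # benzothiazole: 2-R-benzothiazole -> R-COCl + 2-aminothiophenol
  defs$benzothiazole <- .mkdef("benzothiazole", "heterocycle",
    c("acyl_chloride", "aminothiophenol"),
    "[cX3;R2]1[cX3;R2][sX2][cX3][nX2]1",
    c(.ACYL_CL, "[SX2;H1]!@[cX3]:[cX3]!@[NX3;H2]"),
    c("free_amine", "acid_halide", "aldehyde"),
    provenance = "benzothiazole condensation (heterocycle set)")
  eng$benzothiazole <- list(retro = .benzofusedRetro,
                            forward = .benzofusedForward)

  # Hantzsch thiazole: 2-R1-4-R2-thiazole -> thioamide + alpha-bromoketone
  defs$thiazole_hantzsch <- .mkdef("thiazole_hantzsch", "heterocycle",
    c("thioamide", "bromoketone"),
    "[sX2]1[cX3][nX2][cX3][cX3;H1]1",
    c("[CX3](=[SX1])[NX3;H2]", "[CX3](=[OX1])[CX4;H2][Br]"),
    c("free_amine", "acid_halide", "aldehyde"),
    allowance = c(free_amine = 1L),
    provenance = "Hantzsch thiazole synthesis (heterocycle set)")
  eng$thiazole_hantzsch <- list(
    retro = function(mol, map) {
      # map: S1 C2 N3 C4 C5
      mol <- .molDelBond(mol, map[1], map[5])
      mol <- .molDelBond(mol, map[3], map[4])
      mol <- .molSetBond(mol, map[1], map[2], 2)
      mol <- .molSetBond(mol, map[2], map[3], 1)
      mol <- .molSetBond(mol, map[4], map[5], 1)
      mol <- .molAddAtom(mol, "O", to = map[4], order = 2)$mol
      mol <- .molAddAtom(mol, "Br", to = map[5])$mol
      list(.molFragment(mol, map[2]), .molFragment(mol, map[4]))
    },
    forward = function(mols, maps) {
      # A: C2,S1,N3 ; B: C4,O,C5,Br
      cb <- .molCombine(mols[[1]], mols[[2]])
      A <- maps[[1]]; B <- maps[[2]] + cb$offset
      m <- cb$mol
      m <- .molSetBond(m, A[1], A[2], 1)   # S1-C2
      m <- .molSetBond(m, A[1], A[3], 2)   # C2=N3
      m <- .molSetBond(m, B[1], B[3], 2)   # C4=C5
      m <- .molSetBond(m, A[2], B[3], 1)   # S1-C5
      m <- .molSetBond(m, A[3], B[1], 1)   # N3-C4
      .molDelAtoms(m, c(B[2], B[4]))
    })

  # Knorr pyrazole: 1-R-3,5-R'2-pyrazole -> hydrazine + 1,3-diketone
  .DIKETONE13 <- paste0("[CX3;!$([CX3](=[OX1])[!#6;!#1])](=[OX1])",
                        "[CX4;H2][CX3;!$([CX3](=[OX1])[!#6;!#1])]=[OX1]")
  defs$pyrazole <- .mkdef("pyrazole", "heterocycle",
    c("hydrazine", "diketone_13"),
    "[nX3;H1,$([nX3][#6])]1[nX2][cX3][cX3;H1][cX3]1",
    c("[NX3;H1,H2][NX3;H2]", .DIKETONE13),
    c("free_amine", "acid_halide", "aldehyde"),
    provenance = "Knorr pyrazole synthesis (heterocycle set)")
  eng$pyrazole <- list(
    retro = function(mol, map) {
      # map: N1 N2 C3 C4 C5
      mol <- .molDelBond(mol, map[1], map[5])
      mol <- .molDelBond(mol, map[2], map[3])
      mol <- .molSetBond(mol, map[4], map[5], 1)
      mol <- .molAddAtom(mol, "O", to = map[3], order = 2)$mol
      mol <- .molAddAtom(mol, "O", to = map[5], order = 2)$mol
      list(.molFragment(mol, map[1]), .molFragment(mol, map[3]))
    },
    forward = function(mols, maps) {
      # A: N1,N2 ; B: C3,O,C4,C5,O2
      cb <- .molCombine(mols[[1]], mols[[2]])
      A <- maps[[1]]; B <- maps[[2]] + cb$offset
      m <- cb$mol
      m <- .molSetBond(m, A[2], B[1], 2)   # N2=C3
      m <- .molSetBond(m, A[1], B[4], 1)   # N1-C5
      m <- .molSetBond(m, B[3], B[4], 2)   # C4=C5
      m <- .molSetBond(m, B[1], B[3], 1)   # C3-C4
      .molDelAtoms(m, c(B[2], B[5]))
    })

  # Huisgen 1,2,3-triazole (1,4-disubstituted): azide + terminal alkyne
  defs$triazole_huisgen <- .mkdef("triazole_huisgen", "heterocycle",
    c("azide", "alkyne"),
    "[nX3;$([nX3][#6])]1[nX2][nX2][cX3][cX3;H1]1",
    c("[NX2;$([NX2][#6])]=[NX2;+1]=[NX1;-1]", "[CX2;H1]#[CX2;$([CX2][#6])]"),
    c("azide_grp", "terminal_alkyne", "acid_halide"),
    provenance = "copper-catalysed azide-alkyne cycloaddition (heterocycle set)")
  eng$triazole_huisgen <- list(
    retro = function(mol, map) {
      # map: N1 N2 N3 C4 C5
      mol <- .molDelBond(mol, map[1], map[5])
      mol <- .molDelBond(mol, map[3], map[4])
      mol <- .molSetBond(mol, map[1], map[2], 2)
      mol <- .molSetCharge(mol, map[2], 1L)
      mol <- .molSetCharge(mol, map[3], -1L)
      mol <- .molSetBond(mol, map[4], map[5], 3)
      list(.molFragment(mol, map[1]), .molFragment(mol, map[4]))
    },
    forward = function(mols, maps) {
      # A: N1,N2,N3 ; B: C5(terminal), C4
      cb <- .molCombine(mols[[1]], mols[[2]])
      A <- maps[[1]]; B <- maps[[2]] + cb$offset
      m <- cb$mol
      m <- .molSetBond(m, A[1], A[2], 1)
      m <- .molSetCharge(m, A[2], 0L)
      m <- .molSetCharge(m, A[3], 0L)
      m <- .molSetBond(m, A[3], B[2], 1)   # N3-C4
      m <- .molSetBond(m, A[1], B[1], 1)   # N1-C5
      .molSetBond(m, B[1], B[2], 2)        # C4=C5
    })

  # 1,2,4-oxadiazole: amidoxime + acyl chloride
  defs$oxadiazole_124 <- .mkdef("oxadiazole_124", "heterocycle",
    c("amidoxime", "acyl_chloride"),
    "[oX2]1[nX2][cX3][nX2][cX3]1",
    c("[OX2;H1][NX2]=[CX3][NX3;H2]", .ACYL_CL),
    c("free_amine", "acid_halide", "aldehyde"),
    provenance = "1,2,4-oxadiazole from amidoxime + acyl chloride")
  eng$oxadiazole_124 <- list(
    retro = function(mol, map) {
      # map: O1 N2 C3 N4 C5
      mol <- .molDelBond(mol, map[1], map[5])
      mol <- .molDelBond(mol, map[4], map[5])
      mol <- .molSetBond(mol, map[2], map[3], 2)
      mol <- .molSetBond(mol, map[3], map[4], 1)
      mol <- .molAddAtom(mol, "O", to = map[5], order = 2)$mol
      mol <- .molAddAtom(mol, "Cl", to = map[5])$mol
      list(.molFragment(mol, map[3]), .molFragment(mol, map[5]))
    },
    forward = function(mols, maps) {
      # A: O1,N2,C3,N4 ; B: C5,O,Cl
      cb <- .molCombine(mols[[1]], mols[[2]])
      A <- maps[[1]]; B <- maps[[2]] + cb$offset
      m <- cb$mol
      m <- .molSetBond(m, A[1], B[1], 1)   # O1-C5
      m <- .molSetBond(m, A[4], B[1], 2)   # N4=C5
      .molDelAtoms(m, B[2:3])
    })

  # 1,3,4-oxadiazole: acylhydrazide + acyl chloride
  defs$oxadiazole_134 <- .mkdef("oxadiazole_134", "heterocycle",
    c("hydrazide", "acyl_chloride"),
    "[oX2]1[cX3][nX2][nX2][cX3]1",
    c("[CX3](=[OX1])[NX3;H1][NX3;H2]", .ACYL_CL),
    c("free_amine", "acid_halide", "aldehyde"),
    provenance = "1,3,4-oxadiazole cyclodehydration of a diacylhydrazide")
  eng$oxadiazole_134 <- list(
    retro = function(mol, map) {
      # map: O1 C2 N3 N4 C5
      mol <- .molDelBond(mol, map[1], map[5])
      mol <- .molDelBond(mol, map[4], map[5])
      mol <- .molSetBond(mol, map[1], map[2], 2)
      mol <- .molSetBond(mol, map[2], map[3], 1)
      mol <- .molSetBond(mol, map[3], map[4], 1)
      mol <- .molAddAtom(mol, "O", to = map[5], order = 2)$mol
      mol <- .molAddAtom(mol, "Cl", to = map[5])$mol
      list(.molFragment(mol, map[2]), .molFragment(mol, map[5]))
    },
    forward = function(mols, maps) {
      # A: C2,O1,N3,N4 ; B: C5,O,Cl
      cb <- .molCombine(mols[[1]], mols[[2]])
      A <- maps[[1]]; B <- maps[[2]] + cb$offset
      m <- cb$mol
      m <- .molSetBond(m, A[1], A[2], 1)   # C2-O1 becomes ring bond
      m <- .molSetBond(m, A[1], A[3], 2)   # C2=N3
      m <- .molSetBond(m, A[2], B[1], 1)   # O1-C5
      m <- .molSetBond(m, A[4], B[1], 2)   # N4=C5
      .molDelAtoms(m, B[2:3])
    })

  # tetrazole: 5-R-1H-tetrazole -> nitrile (+ azide reagent)
  defs$tetrazole <- .mkdef("tetrazole", "heterocycle", "nitrile",
    "[nX3;H1]1[nX2][nX2][nX2][cX3;$([cX3][#6])]1",
    "[CX2;$([CX2][#6])]#[NX1]",
    c("nitrile_grp", "acid_halide"),
    allowance = c(nitrile_grp = 0L),
    provenance = "tetrazole from nitrile + azide (heterocycle set)")
  eng$tetrazole <- list(
    retro = function(mol, map) {
      # map: N1 N2 N3 N4 C5 ; keep C5-N1 as the nitrile
      mol <- .molSetBond(mol, map[1], map[5], 3)
      mol <- .molDelAtoms(mol, map[2:4])
      list(mol)
    },
    forward = function(mols, maps) {
      # A: C5, N1
      m <- mols[[1]]; A <- maps[[1]]
      m <- .molSetBond(m, A[1], A[2], 1)
      r <- .molAddAtom(m, "N", to = A[2], order = 1); m <- r$mol; n2 <- r$idx
      r <- .molAddAtom(m, "N", to = n2, order = 2); m <- r$mol; n3 <- r$idx
      r <- .molAddAtom(m, "N", to = n3, order = 1); m <- r$mol; n4 <- r$idx
      .molSetBond(m, n4, A[1], 2)
    })

  # quinoxaline: benzene-1,2-diamine + 1,2-diketone
  defs$quinoxaline <- .mkdef("quinoxaline", "heterocycle",
    c("aryl_diamine", "diketone_12"),
    "[nX2]1[cX3][cX3][nX2][cX3;R2][cX3;R2]1",
    c("[NX3;H2]!@[cX3]:[cX3]!@[NX3;H2]",
      "[CX3;$([CX3][#6])](=[OX1])[CX3;$([CX3][#6])]=[OX1]"),
    c("free_amine", "acid_halide", "aldehyde"),
    provenance = "quinoxaline condensation (heterocycle set)")
  eng$quinoxaline <- list(
    retro = function(mol, map) {
      # map: N1 C2 C3 N4 c4a c8a; the fused bond is re-kekulized explicitly
      # because either Kekule assignment of the pyrazine ring is legal input
      mol <- .molDelBond(mol, map[1], map[2])
      mol <- .molDelBond(mol, map[3], map[4])
      mol <- .molSetBond(mol, map[2], map[3], 1)
      mol <- .molSetBond(mol, map[1], map[6], 1)
      mol <- .molSetBond(mol, map[4], map[5], 1)
      mol <- .molSetBond(mol, map[5], map[6], 2)
      mol <- .molAddAtom(mol, "O", to = map[2], order = 2)$mol
      mol <- .molAddAtom(mol, "O", to = map[3], order = 2)$mol
      list(.molFragment(mol, map[1]), .molFragment(mol, map[2]))
    },
    forward = function(mols, maps) {
      # A: N1,c8a,c4a,N4 ; B: C2,O,C3,O2
      cb <- .molCombine(mols[[1]], mols[[2]])
      A <- maps[[1]]; B <- maps[[2]] + cb$offset
      m <- cb$mol
      m <- .molSetBond(m, A[1], B[1], 2)   # N1=C2
      m <- .molSetBond(m, A[4], B[3], 2)   # N4=C3
      m <- .molSetBond(m, B[1], B[3], 1)
      .molDelAtoms(m, c(B[2], B[4]))
    })

  # pyrimidine: amidine + 1,3-diketone
  defs$pyrimidine <- .mkdef("pyrimidine", "heterocycle",
    c("amidine", "diketone_13"),
    "[nX2]1[cX3][nX2][cX3][cX3;H1][cX3]1",
    c("[NX3;H2][CX3]=[NX2;H1]", .DIKETONE13),
    c("free_amine", "acid_halide", "aldehyde"),
    provenance = "pyrimidine condensation (heterocycle set)")
  eng$pyrimidine <- list(
    retro = function(mol, map) {
      # map: N1 C2 N3 C4 C5 C6
      mol <- .molDelBond(mol, map[1], map[6])
      mol <- .molDelBond(mol, map[3], map[4])
      mol <- .molSetBond(mol, map[4], map[5], 1)
      mol <- .molSetBond(mol, map[5], map[6], 1)
      mol <- .molAddAtom(mol, "O", to = map[4], order = 2)$mol
      mol <- .molAddAtom(mol, "O", to = map[6], order = 2)$mol
      list(.molFragment(mol, map[2]), .molFragment(mol, map[5]))
    },
    forward = function(mols, maps) {
      # A: Na(H2),C2,Nb(H1) ; B: C4,O,C5,C6,O2
      cb <- .molCombine(mols[[1]], mols[[2]])
      A <- maps[[1]]; B <- maps[[2]] + cb$offset
      m <- cb$mol
      m <- .molSetBond(m, A[1], B[1], 2)   # Na=C4
      m <- .molSetBond(m, B[1], B[3], 1)   # C4-C5
      m <- .molSetBond(m, B[3], B[4], 2)   # C5=C6
      m <- .molSetBond(m, A[3], B[4], 1)   # Nb-C6
      .molDelAtoms(m, c(B[2], B[5]))
    })

  # Paal-Knorr pyrrole: primary amine + 1,4-diketone
  defs$pyrrole_paal_knorr <- .mkdef("pyrrole_paal_knorr", "heterocycle",
    c("amine", "diketone_14"),
    "[nX3;H1,$([nX3][#6])]1[cX3][cX3;H1][cX3;H1][cX3]1",
    c("[NX3;H2;+0;!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[SX1]);!$([NX3][SX4]);!$([NX3][NX3,NX2,OX2])]",
      "[CX3;$([CX3][#6])](=[OX1])[CX4;H2][CX4;H2][CX3;$([CX3][#6])]=[OX1]"),
    c("free_amine", "acid_halide", "aldehyde"),
    provenance = "Paal-Knorr pyrrole synthesis (heterocycle set)")
  eng$pyrrole_paal_knorr <- list(
    retro = function(mol, map) {
      # map: N1 C2 C3 C4 C5
      mol <- .molDelBond(mol, map[1], map[2])
      mol <- .molDelBond(mol, map[1], map[5])
      mol <- .molSetBond(mol, map[2], map[3], 1)
      mol <- .molSetBond(mol, map[4], map[5], 1)
      mol <- .molAddAtom(mol, "O", to = map[2], order = 2)$mol
      mol <- .molAddAtom(mol, "O", to = map[5], order = 2)$mol
      list(.molFragment(mol, map[1]), .molFragment(mol, map[2]))
    },
    forward = function(mols, maps) {
      # A: N ; B: C2,O,C3,C4,C5,O2
      cb <- .molCombine(mols[[1]], mols[[2]])
      A <- maps[[1]]; B <- maps[[2]] + cb$offset
      m <- cb$mol
      m <- .molSetBond(m, A[1], B[1], 1)
      m <- .molSetBond(m, A[1], B[5], 1)
      m <- .molSetBond(m, B[1], B[3], 2)
      m <- .molSetBond(m, B[4], B[5], 2)
      .molDelAtoms(m, c(B[2], B[6]))
    })

  # 5-amino-oxazole-4-carbonitrile: acyl chloride + aminomalononitrile (fixed
  # reagent; single synthon role)
  defs$aminooxazole_carbonitrile <- .mkdef("aminooxazole_carbonitrile",
    "heterocycle", "acyl_chloride",
    "[oX2]1[cX3][nX2][cX3;$([cX3][CX2]#[NX1])][cX3;$([cX3][NX3;H2])]1",
    .ACYL_CL,
    c("acid_halide", "aldehyde", "free_amine"),
    allowance = c(free_amine = 1L),
    provenance = "aminomalononitrile + acyl chloride oxazole formation (in-house)")
  eng$aminooxazole_carbonitrile <- list(
    retro = function(mol, map) {
      # map: O1 C2 N3 C4 C5; the acyl half is the only returned synthon
      mol <- .molDelBond(mol, map[1], map[2])
      mol <- .molDelBond(mol, map[2], map[3])
      mol <- .molAddAtom(mol, "O", to = map[2], order = 2)$mol
      mol <- .molAddAtom(mol, "Cl", to = map[2])$mol
      list(.molFragment(mol, map[2]))
    },
    forward = function(mols, maps) {
      # A: C2,O1,Cl
      m <- mols[[1]]; A <- maps[[1]]
      m <- .molSetBond(m, A[1], A[2], 1)                    # C2-O1 ring bond
      r <- .molAddAtom(m, "N", to = A[1], order = 2); m <- r$mol; n3 <- r$idx
      r <- .molAddAtom(m, "C", to = n3, order = 1); m <- r$mol; c4 <- r$idx
      r <- .molAddAtom(m, "C", to = c4, order = 2); m <- r$mol; c5 <- r$idx
      m <- .molSetBond(m, c5, A[2], 1)                      # C5-O1
      r <- .molAddAtom(m, "C", to = c4, order = 1); m <- r$mol; cn <- r$idx
      m <- .molAddAtom(m, "N", to = cn, order = 3)$mol      # nitrile
      m <- .molAddAtom(m, "N", to = c5, order = 1)$mol      # 5-amino
      .molDelAtoms(m, A[3])
    })

  list(defs = defs, engines = eng)
}

.builtinCache <- new.env(parent = emptyenv())

.builtin <- function() {
  if (is.null(.builtinCache$lib)) {
    b <- .builtinDefs()
    for (nm in names(b$engines)) .engines[[nm]] <- b$engines[[nm]]
    .builtinCache$lib <- unname(b$defs)
  }
  .builtinCache$lib
}

# ---- loading / exporting the roster -----------------------------------------

#' Load a poised-reaction library
#'
#' With no argument, returns the built-in roster of 21 reactions: 8 linking
#' chemistries (amide, sulfonamide, reductive amination, Suzuki biaryl,
#' Sonogashira, aryl ether O-alkylation, SNAr amination, thiourea) and 13
#' heterocycle formations (benzimidazole, benzoxazole, benzothiazole, Hantzsch
#' thiazole, Knorr pyrazole, Huisgen triazole, 1,2,4- and 1,3,4-oxadiazole,
#' tetrazole, quinoxaline, pyrimidine, Paal-Knorr pyrrole, and the
#' 5-aminooxazole-4-carbonitrile formation). With a YAML file, returns the
#' roster it describes: records may subset, reorder or re-parameterise
#' (patterns, incompatibilities, classes) the built-in chemistries; each
#' record's name must correspond to a transform engine shipped with the
#' package.
#'
#' @param configPath path to a YAML reaction-definition file, or `NULL` for
#'   the built-in library.
#' @return list of [ReactionDefinition-class] objects with unique names.
#' @examples
#' lib <- loadReactionLibrary()
#' length(lib) # 21
#' @export
loadReactionLibrary <- function(configPath = NULL) {
  if (is.null(configPath)) return(.builtin())
  if (!file.exists(configPath)) stop("reaction file not found: ", configPath)
  .builtin() # ensure engines registered
  raw <- yaml::read_yaml(configPath)
  recs <- raw$reactions
  if (is.null(recs)) stop("reaction file has no 'reactions' list")
  nms <- vapply(recs, function(r) r$name %||% NA_character_, character(1))
  if (anyNA(nms) || any(!nzchar(nms))) stop("every reaction needs a name")
  if (anyDuplicated(nms)) stop("duplicate reaction names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  lapply(recs, function(r) {
    if (is.null(.engines[[r$name]]))
      stop("no transform engine for reaction '", r$name, "'")
    for (s in c(r$product_smarts, unlist(r$role_smarts),
                unlist(r$incompatibility))) {
      ok <- try(validateSmarts(s), silent = TRUE)
      if (inherits(ok, "try-error"))
        stop("reaction '", r$name, "': invalid SMARTS: ", s)
    }
    inc <- unlist(r$incompatibility)
    if (is.null(inc)) inc <- character(0)
    alw <- stats::setNames(integer(length(inc)), names(inc))
    ua <- unlist(r$allowance)
    if (!is.null(ua)) alw[names(ua)] <- as.integer(ua)
    new("ReactionDefinition",
        name = r$name, category = r$category,
        synthonClasses = as.character(unlist(r$synthon_classes)),
        productSmarts = r$product_smarts,
        roleSmarts = as.character(unlist(r$role_smarts)),
        incompat = inc, allowance = alw,
        provenance = r$provenance %||% "")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a reaction library as YAML
#'
#' Writes the declarative fields of each definition in the structured format
#' that [loadReactionLibrary()] reads back.
#'
#' @param library list of [ReactionDefinition-class] objects
#' @param path output file path
#' @return `path`, invisibly.
#' @export
writeReactionLibrary <- function(library, path) {
  recs <- lapply(library, function(d) list(
    name = d@name, category = d@category,
    synthon_classes = as.list(d@synthonClasses),
    product_smarts = d@productSmarts,
    role_smarts = as.list(d@roleSmarts),
    incompatibility = as.list(d@incompat),
    allowance = as.list(as.integer(d@allowance)),
    provenance = d@provenance))
  yaml::write_yaml(list(reactions = recs), path)
  invisible(path)
}

.libByName <- function(library) {
  stats::setNames(library, vapply(library, function(d) d@name, character(1)))
}

# ---- classification, deconstruction, forward synthesis ----------------------

#' Classify a fragment as poised
#'
#' Scans a molecule for poised bonds: substructures that one of the library's
#' robust reactions could have formed in a single step. Each symmetry-unique
#' match yields one annotation carrying the synthons the retro transform
#' implies (with commercial leaving-group conventions, e.g. an amide gives
#' the acyl chloride and the amine). An empty result means "not poised".
#'
#' @param smiles a single SMILES string
#' @param library list of [ReactionDefinition-class] (default: built-in 21)
#' @param id fragment identifier carried into the result
#' @return data.frame with columns `fragment_id`, `reaction`,
#'   `matched_atoms` (list column; 0-based indices into the canonical atom
#'   order of the stored SMILES) and `synthons` (list column of canonical
#'   SMILES character vectors), ordered by reaction name then matched-atom
#'   tuple.
#' @examples
#' classifyPoised("CC(=O)NCc1c(Cl)cccc1Cl", id = "cpd2")
#' @export
classifyPoised <- function(smiles, library = loadReactionLibrary(), id = "frag") {
  stopifnot(length(smiles) == 1)
  can <- canonicalSmiles(smiles)
  if (is.na(can)) stop("unparsable SMILES for fragment '", id, "': ", smiles)
  sdf <- .smilesToSDF(can)
  mol <- .parseSDF(sdf)
  lib <- .libByName(library)
  lib <- lib[order(names(lib))]
  pats <- lapply(lib, function(d) d@productSmarts)
  hits <- .obMatchSDF(sdf, pats)
  rows <- list()
  for (nm in names(lib)) {
    maps <- hits[[nm]]
    if (!length(maps)) next
    # symmetry-unique: one annotation per distinct matched-atom set
    keys <- vapply(maps, function(m) paste(sort(m), collapse = ","), character(1))
    maps <- maps[!duplicated(keys)]
    ord <- order(vapply(maps, function(m) paste(sprintf("%04d", sort(m)),
                                                collapse = ","), character(1)))
    maps <- maps[ord]
    eng <- .engines[[nm]]
    for (m in maps) {
      syn <- vapply(eng$retro(mol, m), .molToSmiles, character(1))
      if (anyNA(syn)) next
      rows[[length(rows) + 1L]] <- data.frame(
        fragment_id = id, reaction = nm,
        matched_atoms = I(list(sort(m) - 1L)),
        synthons = I(list(unname(syn))))
    }
  }
  if (!length(rows))
    return(data.frame(fragment_id = character(0), reaction = character(0),
                      matched_atoms = I(list()), synthons = I(list())))
  do.call(rbind, rows)
}

#' Deconstruct a poised fragment into synthons
#'
#' Applies one reaction's retro transform to every symmetry-unique match in
#' the fragment. Synthons follow commercial leaving-group conventions
#' (acyl/sulfonyl chlorides, aryl/alkyl bromides, boronic acids, phenols).
#'
#' @param smiles fragment SMILES
#' @param reactionName name of a reaction in `library`
#' @param library list of [ReactionDefinition-class]
#' @return list of synthon sets (each a character vector of canonical SMILES,
#'   in role order); empty list when the fragment does not match.
#' @examples
#' deconstruct("CC(=O)NCc1c(Cl)cccc1Cl", "amide")
#' @export
deconstruct <- function(smiles, reactionName, library = loadReactionLibrary()) {
  lib <- .libByName(library)
  if (!reactionName %in% names(lib))
    stop("unknown reaction: ", reactionName)
  ann <- classifyPoised(smiles, library = lib[reactionName])
  lapply(ann$synthons, identity)
}

#' Forward-synthesize a product from synthons
#'
#' Applies a reaction's forward transform: each synthon is checked against its
#' role pattern (in role order) and the product graph is assembled. A pure
#' function of its inputs.
#'
#' @param reactionName name of a reaction in `library`
#' @param synthons character vector of synthon SMILES, one per role, in role
#'   order
#' @param library list of [ReactionDefinition-class]
#' @return canonical product SMILES, or `NA` when a synthon fails its role
#'   pattern.
#' @examples
#' forwardSynthesize("amide", c("CC(=O)Cl", "NCc1c(Cl)cccc1Cl"))
#' @export
forwardSynthesize <- function(reactionName, synthons,
                              library = loadReactionLibrary()) {
  lib <- .libByName(library)
  if (!reactionName %in% names(lib))
    stop("unknown reaction: ", reactionName)
  def <- lib[[reactionName]]
  if (length(synthons) != length(def@synthonClasses))
    stop("reaction '", reactionName, "' needs ",
         length(def@synthonClasses), " synthons, got ", length(synthons))
  mols <- list(); maps <- list()
  for (i in seq_along(synthons)) {
    can <- canonicalSmiles(synthons[i])
    if (is.na(can)) return(NA_character_)
    sdf <- .smilesToSDF(can)
    hit <- .obMatchSDF(sdf, list(p = def@roleSmarts[i]))[[1]]
    if (!length(hit)) return(NA_character_)
    mols[[i]] <- .parseSDF(sdf)
    maps[[i]] <- hit[[1]]
  }
  out <- .engines[[def@name]]$forward(mols, maps)
  if (is.null(out)) return(NA_character_)
  .molToSmiles(out)
}
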