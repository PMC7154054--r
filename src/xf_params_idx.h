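/* Parameter index map: order must match names(default_params()) */
#define N_TEMPLATE 177
#define k_ATP P(0)
#define k_Anabolism P(1)
#define k_ACE P(2)
#define vol_cyto P(3)
#define MW_GLC P(4)
#define MW_XYL P(5)
#define MW_ACE P(6)
#define MW_MVA P(7)
#define A_total P(8)
#define AMP_const P(9)
#define N_total P(10)
#define NP_total P(11)
#define PO_ratio P(12)
#define nadph_first_term P(13)
#define vmax_PTS P(14)
#define K_PTS_GLC P(15)
#define K_PTS_PEP P(16)
#define K_PTS_G6P P(17)
#define n_PTS_G6P P(18)
#define vmax_NPTS P(19)
#define K_NPTS_GLC P(20)
#define K_I_NPTS P(21)
#define K_NPTS_G6P P(22)
#define EIIA_total P(23)
#define K_EIIA P(24)
#define vmax_Pgi P(25)
#define K_Pgi_G6P P(26)
#define K_Pgi_F6P P(27)
#define Keq_Pgi P(28)
#define vmax_Pfk P(29)
#define K_Pfk_F6P P(30)
#define K_Pfk_ATP P(31)
#define vmax_Fbp P(32)
#define K_Fbp_FBP P(33)
#define vmax_Fba P(34)
#define K_Fba_FBP P(35)
#define vmax_Emp P(36)
#define K_Emp_GAP P(37)
#define K_Emp_NAD P(38)
#define K_Emp_ADP P(39)
#define Ki_Emp_NADH P(40)
#define n_Emp_NADH P(41)
#define vmax_Pyk P(42)
#define K_Pyk_PEP P(43)
#define K_Pyk_ADP P(44)
#define a0_Pyk P(45)
#define Ka_Pyk_FBP P(46)
#define vmax_Pps P(47)
#define K_Pps_PYR P(48)
#define K_Pps_ATP P(49)
#define vmax_PDH P(50)
#define K_PDH_PYR P(51)
#define K_PDH_NAD P(52)
#define Ki_PDH_NADH P(53)
#define n_PDH_NADH P(54)
#define vmax_Pfl P(55)
#define K_Pfl_PYR P(56)
#define vmax_G6PDH P(57)
#define K_G6PDH_G6P P(58)
#define K_G6PDH_NADP P(59)
#define Ki_G6PDH_NADPH P(60)
#define n_G6PDH_NADPH P(61)
#define vmax_PGDH P(62)
#define K_PGDH_PG6 P(63)
#define K_PGDH_NADP P(64)
#define vmax_Rpe P(65)
#define K_Rpe P(66)
#define Keq_Rpe P(67)
#define vmax_Rpi P(68)
#define K_Rpi P(69)
#define Keq_Rpi P(70)
#define vmax_TktA P(71)
#define K_TktA P(72)
#define Keq_TktA P(73)
#define vmax_Tal P(74)
#define K_Tal P(75)
#define Keq_Tal P(76)
#define vmax_TktB P(77)
#define K_TktB P(78)
#define Keq_TktB P(79)
#define vmax_CS P(80)
#define K_CS_AcCoA P(81)
#define K_CS_OAA P(82)
#define vmax_ICDH P(83)
#define K_ICDH_ICIT P(84)
#define K_ICDH_NADP P(85)
#define vmax_aKGDH P(86)
#define K_aKGDH_AKG P(87)
#define K_aKGDH_NAD P(88)
#define vmax_SDH P(89)
#define K_SDH_SUC P(90)
#define vmax_Fum P(91)
#define K_Fum_FUM P(92)
#define vmax_MDH P(93)
#define K_MDH_MAL P(94)
#define K_MDH_NAD P(95)
#define vmax_Icl P(96)
#define K_Icl_ICIT P(97)
#define vmax_MS P(98)
#define K_MS_GLX P(99)
#define K_MS_AcCoA P(100)
#define vmax_Ppc P(101)
#define K_Ppc_PEP P(102)
#define Ki_Ppc_OAA P(103)
#define vmax_Pck P(104)
#define K_Pck_OAA P(105)
#define K_Pck_ATP P(106)
#define vmax_Mez P(107)
#define K_Mez_MAL P(108)
#define K_Mez_NADP P(109)
#define vmax_PTACK P(110)
#define K_PTACK_AcCoA P(111)
#define K_PTACK_ADP P(112)
#define vmax_Acs P(113)
#define K_Acs_ACE P(114)
#define vmax_LDH P(115)
#define K_LDH_PYR P(116)
#define K_LDH_NADH P(117)
#define vmax_ADH P(118)
#define K_ADH_AcCoA P(119)
#define K_ADH_NADH P(120)
#define vmax_NOX P(121)
#define K_NOX_NADH P(122)
#define n_NOX P(123)
#define vmax_Udh P(124)
#define K_Udh_NADPH P(125)
#define K_Udh_NAD P(126)
#define vmax_resp P(127)
#define K_resp_NADH P(128)
#define K_resp_ADP P(129)
#define vmax_ATPase P(130)
#define K_ATPase_ATP P(131)
#define vmax_XT P(132)
#define K_XYL P(133)
#define K_I P(134)
#define K_XT_ATP P(135)
#define vmax_Xyi P(136)
#define K_XYLin P(137)
#define vmax_Xyk P(138)
#define K_XYLU P(139)
#define K_Xyk_ATP P(140)
#define vmax_AtoB P(141)
#define K_AtoB_AcCoA P(142)
#define n_AtoB P(143)
#define vmax_HMGS P(144)
#define K_HMGS_AcAcCoA P(145)
#define K_HMGS_AcCoA P(146)
#define Ki_HMGS_HMGCoA P(147)
#define Ki_AtoB_AcAcCoA P(148)
#define vmax_HMGR P(149)
#define K_HMGR_HMGCoA P(150)
#define K_HMGR_NADPH P(151)
#define cAMP_max P(152)
#define K_Crp_phi P(153)
#define n_Crp P(154)
#define K_Cra_FBP P(155)
#define n_Cra P(156)
#define K_XylR P(157)
#define n_XylR P(158)
#define K_ArcA P(159)
#define n_ArcA P(160)
#define ArcA_anaerobic P(161)
#define ref_Crp P(162)
#define ref_Cra P(163)
#define ref_ArcA P(164)
#define ref_XylR P(165)
#define bm_G6P P(166)
#define bm_F6P P(167)
#define bm_R5P P(168)
#define bm_E4P P(169)
#define bm_GAP P(170)
#define bm_PEP P(171)
#define bm_PYR P(172)
#define bm_AcCoA P(173)
#define bm_OAA P(174)
#define bm_AKG P(175)
#define bm_ATP P(176)
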