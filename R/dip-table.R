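# Monte-Carlo null quantiles of the dip statistic under the uniform null.
# Generated once by scratch/make_dip_table.R (3000 replicates per sample
# size, seed 20260920) with this package's dip_statistic(); do not edit.
dip_null_table <- list(
  n = c(10, 15, 20, 30, 50, 75, 100, 150, 200, 300, 500, 750, 1000, 1500, 2000, 3000, 5000),
  probs = c(      0,    0.01,    0.02,    0.03,    0.04,    0.05,    0.06,    0.07,    0.08,    0.09,     0.1,    0.11,    0.12,    0.13,    0.14,    0.15,    0.16,    0.17,    0.18,    0.19,     0.2,    0.21,    0.22,    0.23,    0.24,    0.25,    0.26,    0.27,    0.28,    0.29,     0.3,    0.31,    0.32,    0.33,    0.34,    0.35,    0.36,    0.37,    0.38,    0.39,     0.4,    0.41,    0.42,    0.43,    0.44,    0.45,    0.46,    0.47,    0.48,    0.49,     0.5,    0.51,    0.52,    0.53,    0.54,    0.55,    0.56,    0.57,    0.58,    0.59,     0.6,    0.61,    0.62,    0.63,    0.64,    0.65,    0.66,    0.67,    0.68,    0.69,     0.7,    0.71,    0.72,    0.73,    0.74,    0.75,    0.76,    0.77,    0.78,    0.79,     0.8,    0.81,    0.82,    0.83,    0.84,    0.85,    0.86,    0.87,    0.88,    0.89,     0.9,    0.91,    0.92,    0.93,    0.94,    0.95,    0.96,    0.97,    0.98,    0.99,   0.995,   0.999,  0.9995),
  quantiles = matrix(c(
       0.05, 0.0545168, 0.0579469, 0.0602095, 0.0625387, 0.0640246, 0.0654311, 0.066458, 0.0675833, 0.0684354, 0.0692894, 0.0700282, 0.0707909, 0.0715648, 0.0724761, 0.0732884, 0.0738661, 0.0745945, 0.0751966, 0.0758837, 0.0765925, 0.0770074, 0.0776414, 0.078336, 0.0787422, 0.0792696, 0.0797641, 0.0801692, 0.0806908, 0.0811177, 0.0816303, 0.0821448, 0.0826591, 0.0831052, 0.0836071, 0.08404, 0.0844585, 0.0849269, 0.0853215, 0.0856908, 0.0861418, 0.0865917, 0.086821, 0.0871841, 0.0877065, 0.0882579, 0.0887202, 0.0891149, 0.089508, 0.0898296, 0.090129, 0.0904568, 0.0908232, 0.091116, 0.0914542, 0.0918225, 0.0921986, 0.0925654, 0.0928698, 0.0931557, 0.0935093, 0.0937883, 0.0941292, 0.0944209, 0.0946971, 0.0949631, 0.0953747, 0.0956706, 0.0959777, 0.0963693, 0.0966272, 0.0969682, 0.0972664, 0.0975905, 0.0980681, 0.0982945, 0.0985897, 0.0990099, 0.0992851, 0.099695, 0.0999336, 0.100743, 0.101903, 0.102921, 0.10368, 0.104719, 0.105959, 0.107137, 0.108311, 0.109741, 0.111483, 0.113042, 0.114199, 0.116063, 0.118158, 0.120614, 0.123719, 0.125932, 0.129179, 0.13543, 0.14152, 0.151553, 0.155557,
    0.0400577, 0.0516991, 0.0539717, 0.0552196, 0.056445, 0.0574903, 0.0584256, 0.0590726, 0.0596979, 0.0601357, 0.0606472, 0.0609265, 0.0613334, 0.0617029, 0.062085, 0.0624095, 0.0627688, 0.0630918, 0.0634173, 0.0637308, 0.0639855, 0.064291, 0.0645183, 0.0647906, 0.065056, 0.0652811, 0.0656202, 0.065845, 0.0660775, 0.0662357, 0.0664894, 0.0667262, 0.0670268, 0.0674492, 0.0678046, 0.0682108, 0.0686951, 0.0691476, 0.0695475, 0.069828, 0.0701964, 0.0706692, 0.0711172, 0.0714837, 0.0719179, 0.0723687, 0.0727725, 0.0732156, 0.073593, 0.074048, 0.0743922, 0.0747058, 0.0750233, 0.0753993, 0.075661, 0.0759561, 0.0763252, 0.0767223, 0.0770185, 0.0774753, 0.0779104, 0.0782838, 0.078736, 0.0790462, 0.0794935, 0.0801075, 0.0804717, 0.080851, 0.0814633, 0.0818076, 0.0823138, 0.0829873, 0.0834281, 0.0841252, 0.0845692, 0.0849786, 0.085567, 0.0863123, 0.086947, 0.0873623, 0.0879509, 0.0883165, 0.0890652, 0.0898251, 0.0904747, 0.0909705, 0.0916669, 0.0923088, 0.0930864, 0.0939125, 0.0947257, 0.0960668, 0.0972156, 0.0983254, 0.0997839, 0.101387, 0.103549, 0.106421, 0.109762, 0.114845, 0.118665, 0.127016, 0.127614,
    0.039865, 0.0454989, 0.0469378, 0.0476663, 0.0484981, 0.0491844, 0.0495337, 0.050102, 0.0509129, 0.0517264, 0.052369, 0.0528244, 0.0534192, 0.0538218, 0.054094, 0.0543895, 0.0548929, 0.0553405, 0.055769, 0.0560974, 0.0565054, 0.0570343, 0.0573368, 0.0576838, 0.0580393, 0.058331, 0.0586512, 0.0589493, 0.0592992, 0.0595439, 0.0598378, 0.0601336, 0.060544, 0.0608101, 0.0611965, 0.0615262, 0.0618277, 0.0621207, 0.0623678, 0.0626532, 0.0629885, 0.0633139, 0.0636297, 0.0638756, 0.0641857, 0.0644569, 0.0647766, 0.0650382, 0.0653081, 0.0656479, 0.0659333, 0.0661966, 0.0664882, 0.0667715, 0.0670021, 0.0672705, 0.0675235, 0.0678748, 0.0681896, 0.06849, 0.0687708, 0.0690843, 0.0695364, 0.0697961, 0.0701334, 0.0704331, 0.0709319, 0.0713256, 0.0716289, 0.0719623, 0.0724114, 0.0727742, 0.0731816, 0.0735357, 0.0739891, 0.0745566, 0.0751198, 0.0757761, 0.0762653, 0.0768631, 0.0775823, 0.0779831, 0.0783863, 0.0787552, 0.0793008, 0.0797166, 0.080371, 0.0810743, 0.0818003, 0.0825705, 0.0834538, 0.0843772, 0.0852789, 0.0865545, 0.08774, 0.0892168, 0.0905057, 0.0929695, 0.0958926, 0.100778, 0.103268, 0.110267, 0.112665,
    0.0323047, 0.0373963, 0.0391444, 0.040017, 0.0408889, 0.041408, 0.042148, 0.0426037, 0.0431472, 0.0435617, 0.0439627, 0.0443235, 0.0447502, 0.0451595, 0.0454565, 0.0457841, 0.0461557, 0.0465166, 0.0467576, 0.0470137, 0.0472766, 0.0475742, 0.0478846, 0.0481389, 0.0483592, 0.0486096, 0.0488992, 0.0491461, 0.0493978, 0.0496242, 0.0498293, 0.0501301, 0.0504243, 0.0506388, 0.0510069, 0.0512928, 0.051578, 0.0518248, 0.0520884, 0.0523287, 0.0526193, 0.0529409, 0.0531986, 0.0534843, 0.0536392, 0.0538838, 0.0541835, 0.0545779, 0.0548555, 0.0550094, 0.0552223, 0.0554405, 0.0556963, 0.0559988, 0.0562937, 0.0566465, 0.0569558, 0.0572108, 0.0575214, 0.0577568, 0.0580737, 0.0584316, 0.0587372, 0.0589731, 0.0592061, 0.0595835, 0.0599596, 0.0602204, 0.0605468, 0.0608998, 0.061253, 0.0616857, 0.0620453, 0.0623735, 0.0627587, 0.0632245, 0.0636544, 0.0640404, 0.0645006, 0.0648776, 0.0652137, 0.0656868, 0.0661417, 0.0665894, 0.0670124, 0.0674558, 0.0680201, 0.0684944, 0.0690336, 0.0696189, 0.0702538, 0.0710111, 0.0716989, 0.0725608, 0.0735281, 0.0752787, 0.0770363, 0.0786246, 0.0811201, 0.0855746, 0.0888505, 0.099556, 0.103272,
    0.025283, 0.0297076, 0.0309979, 0.0318026, 0.0323836, 0.0330589, 0.0335402, 0.033899, 0.0341844, 0.0344952, 0.0347875, 0.0351965, 0.0355508, 0.0357899, 0.0360989, 0.036378, 0.0366783, 0.0369233, 0.0371984, 0.0374263, 0.0376502, 0.0379104, 0.0381106, 0.0383481, 0.0385145, 0.0386777, 0.038868, 0.0391293, 0.0393265, 0.0395226, 0.0397773, 0.039976, 0.0400861, 0.0402535, 0.040486, 0.0407302, 0.0409474, 0.0411207, 0.0413704, 0.0415371, 0.0417524, 0.0419515, 0.042088, 0.0423062, 0.0424682, 0.0426348, 0.0427941, 0.0430016, 0.0431756, 0.0433824, 0.0435922, 0.0437447, 0.0439588, 0.0441977, 0.0444431, 0.0446368, 0.044864, 0.0450605, 0.0453007, 0.0455034, 0.0456643, 0.0459029, 0.0461193, 0.0463601, 0.0467037, 0.0469231, 0.0471495, 0.0473618, 0.0476309, 0.0478565, 0.0480237, 0.0483249, 0.0485554, 0.0488608, 0.0492452, 0.0495102, 0.0498242, 0.0500749, 0.0503834, 0.0507657, 0.0511741, 0.0515083, 0.0518184, 0.0521672, 0.0526528, 0.0530412, 0.0534674, 0.0541418, 0.0545676, 0.0551797, 0.0556625, 0.0562284, 0.0568389, 0.0574824, 0.0582201, 0.0588953, 0.0600673, 0.061719, 0.0630715, 0.0662304, 0.0688106, 0.0756563, 0.0771154,
    0.0220623, 0.0245393, 0.0257157, 0.0263588, 0.0268622, 0.0272024, 0.0275793, 0.0278651, 0.0281713, 0.0284189, 0.0288356, 0.0291233, 0.0293598, 0.0295857, 0.0298364, 0.0300405, 0.0302541, 0.0304541, 0.0306457, 0.0309037, 0.0311208, 0.0313079, 0.0315292, 0.0317322, 0.0318817, 0.0319916, 0.032129, 0.0322624, 0.0324193, 0.0325467, 0.0327183, 0.0329062, 0.0330349, 0.0332122, 0.0333731, 0.0335052, 0.0336741, 0.0338786, 0.0340869, 0.0342673, 0.0344458, 0.0346544, 0.0347916, 0.0348993, 0.0350259, 0.0351686, 0.0353088, 0.035495, 0.0356408, 0.0357925, 0.0359579, 0.0360939, 0.0362812, 0.0364413, 0.0366302, 0.036775, 0.0369574, 0.037137, 0.0372802, 0.0374447, 0.0376048, 0.0377894, 0.03797, 0.0381983, 0.0383804, 0.0386094, 0.0387815, 0.0389843, 0.0391818, 0.0394323, 0.0396805, 0.0398397, 0.0400263, 0.0402718, 0.0404455, 0.0406885, 0.0409624, 0.0411825, 0.0414168, 0.0417457, 0.0420269, 0.042354, 0.0426956, 0.0430104, 0.0432685, 0.0435544, 0.0438585, 0.0443639, 0.0447266, 0.0451167, 0.0456382, 0.0460498, 0.0465188, 0.0472273, 0.0477127, 0.0486125, 0.0497659, 0.0514219, 0.052906, 0.0552449, 0.0568641, 0.062546, 0.064276,
    0.0183555, 0.0217165, 0.022328, 0.0227096, 0.0234462, 0.0237639, 0.0241095, 0.0244019, 0.0246355, 0.0248784, 0.0251742, 0.0254007, 0.0256337, 0.0258242, 0.0260001, 0.0261695, 0.026418, 0.0266075, 0.0267355, 0.026918, 0.0271588, 0.0273022, 0.0274573, 0.0276067, 0.0277408, 0.027891, 0.0280031, 0.0281725, 0.0283086, 0.0284757, 0.0285762, 0.0287285, 0.0288612, 0.0290035, 0.0291689, 0.0293166, 0.0294718, 0.02963, 0.0298172, 0.0299556, 0.0301255, 0.0302918, 0.0304099, 0.030538, 0.0307087, 0.0307941, 0.0309564, 0.0311089, 0.0312195, 0.0313966, 0.0315278, 0.0316865, 0.0318807, 0.0320028, 0.0322024, 0.0323619, 0.032462, 0.0326531, 0.0327869, 0.0329401, 0.0330909, 0.0332183, 0.0333601, 0.0335864, 0.0337107, 0.0338945, 0.0340961, 0.0342597, 0.0344047, 0.0345542, 0.0347112, 0.0349397, 0.0350941, 0.0352563, 0.0354457, 0.0356843, 0.0359011, 0.0361595, 0.0363294, 0.0366509, 0.0369252, 0.0371943, 0.0374656, 0.0377511, 0.0380952, 0.0384972, 0.0387754, 0.0391033, 0.0395168, 0.0399386, 0.040445, 0.0409643, 0.0412965, 0.0418442, 0.0426097, 0.0434902, 0.0445978, 0.0457469, 0.0477397, 0.0504339, 0.0531156, 0.0581995, 0.0599726,
    0.0145922, 0.0180152, 0.0186738, 0.0190484, 0.0195194, 0.0199557, 0.0202563, 0.020513, 0.0207171, 0.0209268, 0.0211131, 0.0212637, 0.0213954, 0.0215403, 0.0216939, 0.0218721, 0.0219942, 0.0221644, 0.0223047, 0.0224773, 0.0226611, 0.0228045, 0.0229294, 0.0230392, 0.0231266, 0.0232411, 0.0233226, 0.023475, 0.0236162, 0.0237312, 0.0238567, 0.0239898, 0.0240827, 0.0241842, 0.0242893, 0.0243625, 0.0244651, 0.0245999, 0.0246862, 0.0247911, 0.0248766, 0.0249683, 0.0250536, 0.0251962, 0.0253081, 0.0254216, 0.025522, 0.025618, 0.0257534, 0.0258768, 0.025992, 0.0260898, 0.0262381, 0.0263368, 0.0264791, 0.0266098, 0.0267489, 0.026876, 0.0269793, 0.0270744, 0.0272022, 0.0272866, 0.0274437, 0.0275863, 0.0277133, 0.0278408, 0.0279934, 0.0281316, 0.0283034, 0.0284346, 0.0286005, 0.0287284, 0.0288822, 0.029024, 0.0292025, 0.0293831, 0.0295473, 0.0296968, 0.0299275, 0.0300617, 0.0302861, 0.0304873, 0.0306908, 0.0309491, 0.0311223, 0.0313825, 0.0316716, 0.0319817, 0.0323592, 0.0327142, 0.0329743, 0.0334192, 0.0338059, 0.0342724, 0.0346685, 0.0354507, 0.036153, 0.0368846, 0.038347, 0.0401336, 0.0418063, 0.0455856, 0.0459679,
    0.0131059, 0.0153552, 0.0159853, 0.0165067, 0.0168239, 0.0170524, 0.0173088, 0.017503, 0.017737, 0.0179181, 0.018168, 0.0183121, 0.0185777, 0.018743, 0.0188299, 0.0189779, 0.0191144, 0.0192652, 0.0193559, 0.0194917, 0.0196341, 0.0197225, 0.0198283, 0.0199164, 0.0200043, 0.0200949, 0.020179, 0.0203061, 0.020404, 0.0204973, 0.0206064, 0.020703, 0.0208244, 0.0209056, 0.0210198, 0.0211281, 0.021212, 0.021294, 0.0213751, 0.0214729, 0.021563, 0.0216467, 0.0217647, 0.0218745, 0.0219837, 0.0221008, 0.0222177, 0.022334, 0.0224248, 0.0225069, 0.0226195, 0.0227233, 0.0227928, 0.0229334, 0.023036, 0.0231394, 0.0232459, 0.0233706, 0.0234853, 0.0235759, 0.0237061, 0.0238293, 0.0239374, 0.0240825, 0.0242235, 0.0243502, 0.024475, 0.0246023, 0.0247162, 0.0248617, 0.0249828, 0.0251216, 0.0252026, 0.025331, 0.025452, 0.0256085, 0.0257664, 0.0259327, 0.0261179, 0.0263134, 0.0264492, 0.0266759, 0.0268596, 0.0270498, 0.0272814, 0.0275444, 0.02776, 0.0279596, 0.028199, 0.0284794, 0.0287705, 0.0290767, 0.0293111, 0.029832, 0.0303326, 0.0307836, 0.0314842, 0.0320186, 0.0332199, 0.0350239, 0.0371392, 0.0412571, 0.0420353,
    0.0110718, 0.0126156, 0.0132343, 0.0135759, 0.013855, 0.0140276, 0.0142985, 0.0144507, 0.0146416, 0.0148078, 0.0149651, 0.0150676, 0.0151633, 0.0152682, 0.0153867, 0.0155058, 0.015597, 0.0156869, 0.0157829, 0.0158764, 0.0159824, 0.016074, 0.0161647, 0.0162682, 0.0163682, 0.0164787, 0.016565, 0.0166429, 0.0167264, 0.0168295, 0.0169034, 0.017009, 0.0170877, 0.0171851, 0.0172565, 0.0173595, 0.0174183, 0.0174841, 0.0175776, 0.0176726, 0.0177358, 0.0178078, 0.0178963, 0.0179642, 0.0180383, 0.0181262, 0.0182162, 0.0182947, 0.0183523, 0.0184198, 0.0185018, 0.0185902, 0.0186701, 0.0187569, 0.0188423, 0.0189008, 0.0189725, 0.0190627, 0.0191281, 0.0192321, 0.0193132, 0.019421, 0.0195013, 0.0195682, 0.0196713, 0.0197582, 0.0198549, 0.0199819, 0.0200988, 0.0201838, 0.0202957, 0.0204137, 0.0205429, 0.0206527, 0.0207549, 0.0208397, 0.0209667, 0.0210653, 0.0212132, 0.0213672, 0.0215618, 0.0217327, 0.0218459, 0.0220106, 0.0221818, 0.0223199, 0.0225355, 0.0227911, 0.0229313, 0.0231432, 0.0233705, 0.0235906, 0.0239013, 0.0242726, 0.0246577, 0.0251003, 0.0256299, 0.0262958, 0.0271677, 0.0286566, 0.0301184, 0.0345656, 0.0349329,
    0.00877934, 0.00999125, 0.0103112, 0.0105415, 0.0107611, 0.010865, 0.0110986, 0.0112228, 0.0113498, 0.0114744, 0.0115983, 0.0116988, 0.0118059, 0.0119034, 0.0120276, 0.0121199, 0.0122312, 0.0123254, 0.0123948, 0.0124679, 0.0125459, 0.0126082, 0.0126814, 0.012755, 0.0128112, 0.0128935, 0.0129864, 0.0130618, 0.0131169, 0.0132063, 0.0132717, 0.0133311, 0.0133883, 0.0134589, 0.0135312, 0.0136237, 0.0136938, 0.0137566, 0.0138186, 0.0138911, 0.0139519, 0.0139899, 0.0140355, 0.0140869, 0.0141475, 0.0142106, 0.0142607, 0.0143147, 0.0143829, 0.01446, 0.0145216, 0.0145949, 0.0146717, 0.0147183, 0.014772, 0.014819, 0.0148988, 0.0149918, 0.0150477, 0.0151011, 0.0151722, 0.0152332, 0.0153074, 0.0153701, 0.0154477, 0.0155289, 0.0156021, 0.0156753, 0.0157639, 0.0158483, 0.015929, 0.0160178, 0.0161046, 0.0162165, 0.0163194, 0.0164224, 0.0165831, 0.0166546, 0.0167451, 0.0168515, 0.0169931, 0.0170799, 0.0172139, 0.017339, 0.0174685, 0.0175755, 0.017694, 0.0178394, 0.0179799, 0.0181248, 0.0183047, 0.0185576, 0.0187819, 0.0190237, 0.0193305, 0.0197007, 0.0200569, 0.0206291, 0.0210284, 0.0218563, 0.0230643, 0.024788, 0.0252621,
    0.00671802, 0.00807988, 0.00856522, 0.00878468, 0.00889355, 0.00904705, 0.0091662, 0.00929162, 0.00938565, 0.00948598, 0.00957457, 0.00966065, 0.00976737, 0.00984238, 0.00992897, 0.0100097, 0.0100897, 0.0101436, 0.0102129, 0.0102896, 0.0103478, 0.0104135, 0.0104842, 0.0105372, 0.0105755, 0.0106289, 0.0106786, 0.0107385, 0.0107924, 0.010831, 0.0108828, 0.010923, 0.0109748, 0.0110073, 0.0110645, 0.0111054, 0.0111358, 0.0111724, 0.0112049, 0.0112779, 0.0113223, 0.0114005, 0.0114653, 0.0115026, 0.0115566, 0.0116152, 0.0116797, 0.0117262, 0.0118084, 0.0118572, 0.0118909, 0.0119535, 0.0120023, 0.0120426, 0.0120992, 0.0121789, 0.0122222, 0.0122755, 0.0123187, 0.0123761, 0.012419, 0.0124784, 0.0125384, 0.012576, 0.0126299, 0.012689, 0.0127425, 0.0127898, 0.0128503, 0.0129135, 0.0129879, 0.0130317, 0.0131111, 0.0131853, 0.013245, 0.0133216, 0.0134003, 0.0134869, 0.0135934, 0.0136843, 0.0137997, 0.0139111, 0.014021, 0.0141495, 0.0142305, 0.0143547, 0.0145072, 0.0146604, 0.0147699, 0.0148911, 0.0150233, 0.0152211, 0.015438, 0.0156177, 0.0158942, 0.0161361, 0.016433, 0.016914, 0.0173067, 0.0181887, 0.0193205, 0.0214262, 0.021778,
    0.00634659, 0.00703395, 0.00734735, 0.00755805, 0.00769159, 0.00781441, 0.00788439, 0.00799439, 0.00808696, 0.00819805, 0.00827918, 0.00834519, 0.00842306, 0.0084778, 0.00853533, 0.00858147, 0.00864302, 0.0087003, 0.00875618, 0.00880522, 0.00886853, 0.00896647, 0.00902552, 0.00907839, 0.00912607, 0.00916756, 0.00921071, 0.00926458, 0.00930836, 0.00935495, 0.00939883, 0.00944949, 0.00950479, 0.00956155, 0.00962305, 0.00965822, 0.00970154, 0.00974564, 0.00979674, 0.0098633, 0.0099158, 0.00997054, 0.0100148, 0.0100572, 0.0100923, 0.0101359, 0.0101796, 0.0102291, 0.0102619, 0.010297, 0.010349, 0.0103991, 0.0104382, 0.0104921, 0.0105501, 0.0105975, 0.0106344, 0.0106822, 0.0107281, 0.0107756, 0.0108215, 0.0108902, 0.0109471, 0.0109852, 0.0110232, 0.0110788, 0.011131, 0.0111828, 0.011242, 0.011318, 0.0114042, 0.0114505, 0.0115082, 0.0115788, 0.0116457, 0.0117069, 0.0117578, 0.0118196, 0.0119019, 0.0119834, 0.0120511, 0.0121119, 0.0121943, 0.0122828, 0.0123751, 0.0124602, 0.0125595, 0.0126638, 0.0127683, 0.0128865, 0.0130532, 0.013183, 0.0133485, 0.0135272, 0.0137953, 0.0139759, 0.0141804, 0.0145253, 0.0149775, 0.015751, 0.0164587, 0.0179212, 0.018504,
    0.00485584, 0.00582429, 0.00608865, 0.00624261, 0.00637943, 0.00646107, 0.00656458, 0.00661311, 0.00668062, 0.00673739, 0.00680228, 0.00688345, 0.00695436, 0.00699614, 0.00704884, 0.00710353, 0.00714977, 0.00718373, 0.00721791, 0.0072608, 0.00730725, 0.007353, 0.00739237, 0.00743338, 0.00746902, 0.00749495, 0.00753238, 0.00757193, 0.00762016, 0.00765577, 0.00769027, 0.00771893, 0.00774807, 0.00779287, 0.00783628, 0.007881, 0.00791675, 0.00795944, 0.00798958, 0.00802701, 0.00806074, 0.00810956, 0.00813964, 0.00817836, 0.00821102, 0.00825079, 0.00829797, 0.00833557, 0.00837841, 0.00842033, 0.00846947, 0.00850164, 0.00854925, 0.00859411, 0.00864318, 0.00869438, 0.00872542, 0.0087707, 0.0088079, 0.0088436, 0.00887685, 0.0089104, 0.00895305, 0.00899632, 0.00904141, 0.00907272, 0.00910724, 0.00914958, 0.00919578, 0.00925394, 0.00930206, 0.00935642, 0.00941163, 0.00946035, 0.0095188, 0.00956875, 0.00962656, 0.00966545, 0.00971425, 0.00978177, 0.00985121, 0.00992612, 0.00996488, 0.0100287, 0.0100996, 0.0101889, 0.0102766, 0.0103599, 0.0104691, 0.0105581, 0.010656, 0.0107631, 0.0108935, 0.011067, 0.0111745, 0.0113646, 0.0115402, 0.0118963, 0.0122589, 0.0128908, 0.013316, 0.0152576, 0.0155284,
    0.00422007, 0.00510585, 0.00522757, 0.00539279, 0.00551464, 0.00561985, 0.00571021, 0.00577488, 0.00582785, 0.00588525, 0.00594424, 0.00600024, 0.00603721, 0.00609468, 0.00613125, 0.00616974, 0.00621615, 0.00625068, 0.00629614, 0.00633704, 0.00636463, 0.00640791, 0.00644551, 0.00648598, 0.00653042, 0.00655346, 0.00659922, 0.00663901, 0.00667891, 0.00670442, 0.00673204, 0.00676009, 0.00679818, 0.00683352, 0.00687042, 0.00691363, 0.00695189, 0.00698022, 0.00701172, 0.00705203, 0.0070915, 0.00712422, 0.00715771, 0.00718435, 0.00721706, 0.00726032, 0.00728968, 0.00731361, 0.00735013, 0.00738722, 0.00742238, 0.00745077, 0.00747986, 0.00750536, 0.00753529, 0.00756753, 0.00759992, 0.00762854, 0.0076568, 0.00768357, 0.00771865, 0.00775032, 0.00778677, 0.0078283, 0.00785307, 0.0078961, 0.0079286, 0.00795811, 0.00799396, 0.00804168, 0.00808062, 0.0081339, 0.00819967, 0.00823722, 0.00829038, 0.00833693, 0.00837385, 0.0084119, 0.00847737, 0.00851806, 0.00859837, 0.00865568, 0.00871459, 0.00879205, 0.00886964, 0.00892723, 0.0090221, 0.0091166, 0.00921679, 0.00929328, 0.00937208, 0.00946469, 0.00959853, 0.00968821, 0.00986103, 0.00998925, 0.0101332, 0.0103416, 0.0107243, 0.0112687, 0.0115283, 0.0125557, 0.0130977,
    0.00362384, 0.00413928, 0.00430415, 0.00445532, 0.00455677, 0.00461908, 0.00469924, 0.00476789, 0.00481167, 0.00485622, 0.00489181, 0.00493324, 0.0049722, 0.0050143, 0.00504304, 0.00507543, 0.00510287, 0.00512986, 0.00515803, 0.00519122, 0.00521367, 0.00524211, 0.00528115, 0.00530517, 0.00534282, 0.00537135, 0.00539222, 0.00541795, 0.00544108, 0.00547157, 0.00549403, 0.00551883, 0.00554179, 0.0055644, 0.00558543, 0.00560674, 0.00563958, 0.0056722, 0.00570174, 0.00573254, 0.00575222, 0.00577624, 0.0057985, 0.00582083, 0.00584813, 0.00586743, 0.00589424, 0.00591587, 0.00594125, 0.00596179, 0.00599957, 0.00602705, 0.00605575, 0.00608316, 0.00611265, 0.00613238, 0.0061672, 0.00618823, 0.0062152, 0.0062489, 0.00627606, 0.00629704, 0.00632885, 0.00635783, 0.00638939, 0.00641666, 0.00643834, 0.0064697, 0.00650689, 0.00654823, 0.00657791, 0.00661087, 0.00664823, 0.00667889, 0.00673295, 0.00676937, 0.00679835, 0.00682992, 0.00686769, 0.00690135, 0.00695012, 0.00699333, 0.00704586, 0.00711034, 0.00716415, 0.00720907, 0.00725262, 0.00731131, 0.0073846, 0.00745413, 0.00752247, 0.00761115, 0.00772339, 0.00785037, 0.00794991, 0.00806207, 0.00822456, 0.00842412, 0.00864894, 0.00908073, 0.00936558, 0.00994494, 0.0100796,
    0.00262814, 0.00319988, 0.00335543, 0.00345, 0.00351255, 0.00357657, 0.00362303, 0.00366382, 0.0037054, 0.00374818, 0.00378181, 0.00380968, 0.00383937, 0.00387214, 0.00390235, 0.00392498, 0.00395111, 0.00397844, 0.00400749, 0.00403612, 0.00406202, 0.00408114, 0.00410979, 0.00413491, 0.00415943, 0.00417867, 0.00420108, 0.00421801, 0.00424047, 0.00425714, 0.0042763, 0.00429311, 0.00431381, 0.00433031, 0.00434998, 0.00436767, 0.00438709, 0.00440204, 0.00442156, 0.00443932, 0.00446387, 0.00448427, 0.00450905, 0.00452476, 0.004548, 0.00456382, 0.0045846, 0.00460596, 0.00463335, 0.00464969, 0.00467557, 0.00469598, 0.00471679, 0.00473785, 0.0047541, 0.00478284, 0.00480727, 0.00482853, 0.00485108, 0.00487145, 0.00489305, 0.00491602, 0.00493946, 0.00496699, 0.00498449, 0.00500747, 0.00503094, 0.00505292, 0.00507801, 0.00510247, 0.00512844, 0.0051516, 0.00518432, 0.00521715, 0.00524692, 0.00527496, 0.00530847, 0.00533951, 0.00536402, 0.00539897, 0.00543181, 0.00545257, 0.00548684, 0.00551898, 0.00554756, 0.00559995, 0.00563188, 0.0056834, 0.00573982, 0.00578736, 0.00585438, 0.00591611, 0.00597004, 0.00605827, 0.00615313, 0.00625602, 0.00637868, 0.00653829, 0.00679918, 0.00712958, 0.00737414, 0.00807543, 0.00830279
  ), nrow = 17, byrow = TRUE)
)
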