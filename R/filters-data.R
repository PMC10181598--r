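# Filter-bank coefficient tables for the supported wavelet families.
# Each entry stores the decomposition and reconstruction lowpass filters of
# the standard two-channel filter bank; the highpass pair is derived by the
# alternating-sign (alias-cancellation) relations in `wavelet_filters()`.
# Orthogonal families store the usual minimum-phase/least-asymmetric
# orthonormal filters; bior/rbio store the spline biorthogonal pairs
# (zero-padded to a common even length). The discrete Meyer filter is not
# tabulated here: it is synthesised at first use (see filters-meyer.R).
.filter_bank <- list(
  "haar" = list(
    dec_lo = c(
      0.7071067811865476, 0.7071067811865476),
    rec_lo = c(
      0.7071067811865476, 0.7071067811865476)
  ),
  "coif1" = list(
    dec_lo = c(
      -0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
      0.8525720202116004, 0.3378976624574818, -0.07273261951252645),
    rec_lo = c(
      -0.07273261951252645, 0.3378976624574818, 0.8525720202116004,
      0.3848648468648578, -0.07273261951252645, -0.015655728135791993)
  ),
  "coif2" = list(
    dec_lo = c(
      -0.000720549445520347, -0.0018232088709110323, 0.005611434819368834,
      0.02368017194684777, -0.05943441864643109, -0.07648859907828076,
      0.4170051844232391, 0.8127236354494135, 0.3861100668227629,
      -0.0673725547237256, -0.04146493678687178, 0.01638733646320364),
    rec_lo = c(
      0.01638733646320364, -0.04146493678687178, -0.0673725547237256,
      0.3861100668227629, 0.8127236354494135, 0.4170051844232391,
      -0.07648859907828076, -0.05943441864643109, 0.02368017194684777,
      0.005611434819368834, -0.0018232088709110323, -0.000720549445520347)
  ),
  "coif3" = list(
    dec_lo = c(
      -3.459977319727278e-05, -7.0983302506379e-05, 0.0004662169598204029,
      0.0011175187708306303, -0.0025745176881367972, -0.009007976136730624,
      0.015880544863669452, 0.03455502757329774, -0.08230192710629983,
      -0.07179982161915484, 0.42848347637737, 0.7937772226260872,
      0.40517690240911824, -0.06112339000297255, -0.06577191128146936,
      0.023452696142077168, 0.007782596425672746, -0.003793512864380802),
    rec_lo = c(
      -0.003793512864380802, 0.007782596425672746, 0.023452696142077168,
      -0.06577191128146936, -0.06112339000297255, 0.40517690240911824,
      0.7937772226260872, 0.42848347637737, -0.07179982161915484,
      -0.08230192710629983, 0.03455502757329774, 0.015880544863669452,
      -0.009007976136730624, -0.0025745176881367972, 0.0011175187708306303,
      0.0004662169598204029, -7.0983302506379e-05, -3.459977319727278e-05)
  ),
  "coif4" = list(
    dec_lo = c(
      -1.7849909144933469e-06, -3.259647940030751e-06,
      3.1229861599195265e-05, 6.233885431278719e-05, -0.0002599743371222568,
      -0.0005890202246332165, 0.0012665610789256603, 0.0037514346971460866,
      -0.0056582838001308835, -0.015211728187697211, 0.02508225333794961,
      0.03933442260558915, -0.09622042453595264, -0.06662747236681717,
      0.43438603311435653, 0.7822389344242826, 0.41530842700068227,
      -0.05607731960356926, -0.08126671024919373, 0.02668230466960483,
      0.01606894713157503, -0.007346167936268051, -0.001629492425226786,
      0.000892313902537003),
    rec_lo = c(
      0.000892313902537003, -0.001629492425226786, -0.007346167936268051,
      0.01606894713157503, 0.02668230466960483, -0.08126671024919373,
      -0.05607731960356926, 0.41530842700068227, 0.7822389344242826,
      0.43438603311435653, -0.06662747236681717, -0.09622042453595264,
      0.03933442260558915, 0.02508225333794961, -0.015211728187697211,
      -0.0056582838001308835, 0.0037514346971460866, 0.0012665610789256603,
      -0.0005890202246332165, -0.0002599743371222568, 6.233885431278719e-05,
      3.1229861599195265e-05, -3.259647940030751e-06,
      -1.7849909144933469e-06)
  ),
  "coif5" = list(
    dec_lo = c(
      -9.604010112767894e-08, -1.6237995172048338e-07,
      2.0612203985788783e-06, 3.7007277113394796e-06,
      -2.1270221672515614e-05, -4.12198619242655e-05, 0.00014035632812373243,
      0.0003018579416682448, -0.0006375589261258812, -0.0016616273039298788,
      0.0024315754425382886, 0.006761520220620417, -0.009159507338676163,
      -0.019758391600965465, 0.032674799467057355, 0.041287530472117834,
      -0.10556315130733723, -0.06203775157498196, 0.4379823066591634,
      0.7742936228603274, 0.42157126673075435, -0.052046670253554764,
      -0.09192158806008609, 0.028169744270532353, 0.023408322118927783,
      -0.010131584846900276, -0.00415931262757864, 0.0021782943778456947,
      0.0003585777411617577, -0.000212081862067494),
    rec_lo = c(
      -0.000212081862067494, 0.0003585777411617577, 0.0021782943778456947,
      -0.00415931262757864, -0.010131584846900276, 0.023408322118927783,
      0.028169744270532353, -0.09192158806008609, -0.052046670253554764,
      0.42157126673075435, 0.7742936228603274, 0.4379823066591634,
      -0.06203775157498196, -0.10556315130733723, 0.041287530472117834,
      0.032674799467057355, -0.019758391600965465, -0.009159507338676163,
      0.006761520220620417, 0.0024315754425382886, -0.0016616273039298788,
      -0.0006375589261258812, 0.0003018579416682448, 0.00014035632812373243,
      -4.12198619242655e-05, -2.1270221672515614e-05, 3.7007277113394796e-06,
      2.0612203985788783e-06, -1.6237995172048338e-07,
      -9.604010112767894e-08)
  ),
  "sym2" = list(
    dec_lo = c(
      -0.12940952255092145, 0.22414386804185735, 0.836516303737469,
      0.48296291314469025),
    rec_lo = c(
      0.48296291314469025, 0.836516303737469, 0.22414386804185735,
      -0.12940952255092145)
  ),
  "sym3" = list(
    dec_lo = c(
      0.035226291882100656, -0.08544127388224149, -0.13501102001039084,
      0.4598775021193313, 0.8068915093133388, 0.3326705529509569),
    rec_lo = c(
      0.3326705529509569, 0.8068915093133388, 0.4598775021193313,
      -0.13501102001039084, -0.08544127388224149, 0.035226291882100656)
  ),
  "sym4" = list(
    dec_lo = c(
      -0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
      0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
      -0.012603967262037833, 0.0322231006040427),
    rec_lo = c(
      0.0322231006040427, -0.012603967262037833, -0.09921954357684722,
      0.29785779560527736, 0.8037387518059161, 0.49761866763201545,
      -0.02963552764599851, -0.07576571478927333)
  ),
  "sym5" = list(
    dec_lo = c(
      0.027333068345077982, 0.029519490925774643, -0.039134249302383094,
      0.1993975339773936, 0.7234076904024206, 0.6339789634582119,
      0.01660210576452232, -0.17532808990845047, -0.021101834024758855,
      0.019538882735286728),
    rec_lo = c(
      0.019538882735286728, -0.021101834024758855, -0.17532808990845047,
      0.01660210576452232, 0.6339789634582119, 0.7234076904024206,
      0.1993975339773936, -0.039134249302383094, 0.029519490925774643,
      0.027333068345077982)
  ),
  "sym6" = list(
    dec_lo = c(
      0.015404109327027373, 0.0034907120842174702, -0.11799011114819057,
      -0.048311742585633, 0.4910559419267466, 0.787641141030194,
      0.3379294217276218, -0.07263752278646252, -0.021060292512300564,
      0.04472490177066578, 0.0017677118642428036, -0.007800708325034148),
    rec_lo = c(
      -0.007800708325034148, 0.0017677118642428036, 0.04472490177066578,
      -0.021060292512300564, -0.07263752278646252, 0.3379294217276218,
      0.787641141030194, 0.4910559419267466, -0.048311742585633,
      -0.11799011114819057, 0.0034907120842174702, 0.015404109327027373)
  ),
  "sym7" = list(
    dec_lo = c(
      0.002681814568257878, -0.0010473848886829163, -0.01263630340325193,
      0.03051551316596357, 0.0678926935013727, -0.049552834937127255,
      0.017441255086855827, 0.5361019170917628, 0.767764317003164,
      0.2886296317515146, -0.14004724044296152, -0.10780823770381774,
      0.004010244871533663, 0.010268176708511255),
    rec_lo = c(
      0.010268176708511255, 0.004010244871533663, -0.10780823770381774,
      -0.14004724044296152, 0.2886296317515146, 0.767764317003164,
      0.5361019170917628, 0.017441255086855827, -0.049552834937127255,
      0.0678926935013727, 0.03051551316596357, -0.01263630340325193,
      -0.0010473848886829163, 0.002681814568257878)
  ),
  "sym8" = list(
    dec_lo = c(
      -0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
      0.007607487324917605, -0.1432942383508097, -0.061273359067658524,
      0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
      -0.05194583810770904, -0.027219029917056003, 0.049137179673607506,
      0.003808752013890615, -0.01495225833704823, -0.0003029205147213668,
      0.0018899503327594609),
    rec_lo = c(
      0.0018899503327594609, -0.0003029205147213668, -0.01495225833704823,
      0.003808752013890615, 0.049137179673607506, -0.027219029917056003,
      -0.05194583810770904, 0.3644418948353314, 0.7771857517005235,
      0.4813596512583722, -0.061273359067658524, -0.1432942383508097,
      0.007607487324917605, 0.03169508781149298, -0.0005421323317911481,
      -0.0033824159510061256)
  ),
  "bior1.1" = list(
    dec_lo = c(
      0.7071067811865476, 0.7071067811865476),
    rec_lo = c(
      0.7071067811865476, 0.7071067811865476)
  ),
  "bior1.3" = list(
    dec_lo = c(
      -0.08838834764831845, 0.08838834764831845, 0.7071067811865476,
      0.7071067811865476, 0.08838834764831845, -0.08838834764831845),
    rec_lo = c(
      0.0, 0.0, 0.7071067811865476, 0.7071067811865476, 0.0, 0.0)
  ),
  "bior1.5" = list(
    dec_lo = c(
      0.016572815184059706, -0.016572815184059706, -0.12153397801643785,
      0.12153397801643785, 0.7071067811865476, 0.7071067811865476,
      0.12153397801643785, -0.12153397801643785, -0.016572815184059706,
      0.016572815184059706),
    rec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.7071067811865476, 0.7071067811865476, 0.0, 0.0,
      0.0, 0.0)
  ),
  "bior2.2" = list(
    dec_lo = c(
      0.0, -0.1767766952966369, 0.3535533905932738, 1.0606601717798212,
      0.3535533905932738, -0.1767766952966369),
    rec_lo = c(
      0.0, 0.3535533905932738, 0.7071067811865476, 0.3535533905932738, 0.0,
      0.0)
  ),
  "bior2.4" = list(
    dec_lo = c(
      0.0, 0.03314563036811941, -0.06629126073623882, -0.1767766952966369,
      0.4198446513295126, 0.9943689110435825, 0.4198446513295126,
      -0.1767766952966369, -0.06629126073623882, 0.03314563036811941),
    rec_lo = c(
      0.0, 0.0, 0.0, 0.3535533905932738, 0.7071067811865476,
      0.3535533905932738, 0.0, 0.0, 0.0, 0.0)
  ),
  "bior2.6" = list(
    dec_lo = c(
      0.0, -0.006905339660024878, 0.013810679320049757, 0.04695630968816917,
      -0.1077232986963881, -0.16987135563661201, 0.4474660099696121,
      0.966747552403483, 0.4474660099696121, -0.16987135563661201,
      -0.1077232986963881, 0.04695630968816917, 0.013810679320049757,
      -0.006905339660024878),
    rec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.0, 0.3535533905932738, 0.7071067811865476,
      0.3535533905932738, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0)
  ),
  "bior2.8" = list(
    dec_lo = c(
      0.0, 0.0015105430506304422, -0.0030210861012608843,
      -0.012947511862546647, 0.02891610982635418, 0.05299848189069094,
      -0.13491307360773605, -0.16382918343409023, 0.46257144047591653,
      0.9516421218971786, 0.46257144047591653, -0.16382918343409023,
      -0.13491307360773605, 0.05299848189069094, 0.02891610982635418,
      -0.012947511862546647, -0.0030210861012608843, 0.0015105430506304422),
    rec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.3535533905932738,
      0.7071067811865476, 0.3535533905932738, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0,
      0.0, 0.0)
  ),
  "bior3.1" = list(
    dec_lo = c(
      -0.3535533905932738, 1.0606601717798212, 1.0606601717798212,
      -0.3535533905932738),
    rec_lo = c(
      0.1767766952966369, 0.5303300858899106, 0.5303300858899106,
      0.1767766952966369)
  ),
  "bior3.3" = list(
    dec_lo = c(
      0.06629126073623882, -0.1988737822087165, -0.15467960838455727,
      0.9943689110435825, 0.9943689110435825, -0.15467960838455727,
      -0.1988737822087165, 0.06629126073623882),
    rec_lo = c(
      0.0, 0.0, 0.1767766952966369, 0.5303300858899106, 0.5303300858899106,
      0.1767766952966369, 0.0, 0.0)
  ),
  "bior3.5" = list(
    dec_lo = c(
      -0.013810679320049757, 0.04143203796014927, 0.052480581416189075,
      -0.26792717880896527, -0.07181553246425873, 0.966747552403483,
      0.966747552403483, -0.07181553246425873, -0.26792717880896527,
      0.052480581416189075, 0.04143203796014927, -0.013810679320049757),
    rec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.1767766952966369, 0.5303300858899106,
      0.5303300858899106, 0.1767766952966369, 0.0, 0.0, 0.0, 0.0)
  ),
  "bior3.7" = list(
    dec_lo = c(
      0.0030210861012608843, -0.009063258303782653, -0.01683176542131064,
      0.074663985074019, 0.03133297870736289, -0.301159125922835,
      -0.02649924094534547, 0.9516421218971786, 0.9516421218971786,
      -0.02649924094534547, -0.301159125922835, 0.03133297870736289,
      0.074663985074019, -0.01683176542131064, -0.009063258303782653,
      0.0030210861012608843),
    rec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.1767766952966369, 0.5303300858899106,
      0.5303300858899106, 0.1767766952966369, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0)
  ),
  "bior3.9" = list(
    dec_lo = c(
      -0.0006797443727836989, 0.002039233118351097, 0.005060319219611981,
      -0.020618912641105536, -0.014112787930175844, 0.09913478249423216,
      0.012300136269419315, -0.32019196836077857, 0.0020500227115698858,
      0.9421257006782068, 0.9421257006782068, 0.0020500227115698858,
      -0.32019196836077857, 0.012300136269419315, 0.09913478249423216,
      -0.014112787930175844, -0.020618912641105536, 0.005060319219611981,
      0.002039233118351097, -0.0006797443727836989),
    rec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.1767766952966369,
      0.5303300858899106, 0.5303300858899106, 0.1767766952966369, 0.0, 0.0,
      0.0, 0.0, 0.0, 0.0, 0.0, 0.0)
  ),
  "bior4.4" = list(
    dec_lo = c(
      0.0, 0.03782845550726404, -0.023849465019556843, -0.11062440441843718,
      0.37740285561283066, 0.8526986790088938, 0.37740285561283066,
      -0.11062440441843718, -0.023849465019556843, 0.03782845550726404),
    rec_lo = c(
      0.0, -0.06453888262869706, -0.04068941760916406, 0.41809227322161724,
      0.7884856164055829, 0.41809227322161724, -0.04068941760916406,
      -0.06453888262869706, 0.0, 0.0)
  ),
  "bior5.5" = list(
    dec_lo = c(
      0.0, 0.0, 0.03968708834740544, 0.007948108637240322,
      -0.05446378846823691, 0.34560528195603346, 0.7366601814282105,
      0.34560528195603346, -0.05446378846823691, 0.007948108637240322,
      0.03968708834740544, 0.0),
    rec_lo = c(
      0.013456709459118716, -0.002694966880111507, -0.13670658466432914,
      -0.09350469740093886, 0.47680326579848425, 0.8995061097486484,
      0.47680326579848425, -0.09350469740093886, -0.13670658466432914,
      -0.002694966880111507, 0.013456709459118716, 0.0)
  ),
  "bior6.8" = list(
    dec_lo = c(
      0.0, 0.0019088317364812906, -0.0019142861290887667,
      -0.016990639867602342, 0.01193456527972926, 0.04973290349094079,
      -0.07726317316720414, -0.09405920349573646, 0.4207962846098268,
      0.8259229974584023, 0.4207962846098268, -0.09405920349573646,
      -0.07726317316720414, 0.04973290349094079, 0.01193456527972926,
      -0.016990639867602342, -0.0019142861290887667, 0.0019088317364812906),
    rec_lo = c(
      0.0, 0.0, 0.0, 0.014426282505624435, 0.014467504896790148,
      -0.07872200106262882, -0.04036797903033992, 0.41784910915027457,
      0.7589077294536541, 0.41784910915027457, -0.04036797903033992,
      -0.07872200106262882, 0.014467504896790148, 0.014426282505624435, 0.0,
      0.0, 0.0, 0.0)
  ),
  "rbio1.1" = list(
    dec_lo = c(
      0.7071067811865476, 0.7071067811865476),
    rec_lo = c(
      0.7071067811865476, 0.7071067811865476)
  ),
  "rbio1.3" = list(
    dec_lo = c(
      0.0, 0.0, 0.7071067811865476, 0.7071067811865476, 0.0, 0.0),
    rec_lo = c(
      -0.08838834764831845, 0.08838834764831845, 0.7071067811865476,
      0.7071067811865476, 0.08838834764831845, -0.08838834764831845)
  ),
  "rbio1.5" = list(
    dec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.7071067811865476, 0.7071067811865476, 0.0, 0.0,
      0.0, 0.0),
    rec_lo = c(
      0.016572815184059706, -0.016572815184059706, -0.12153397801643785,
      0.12153397801643785, 0.7071067811865476, 0.7071067811865476,
      0.12153397801643785, -0.12153397801643785, -0.016572815184059706,
      0.016572815184059706)
  ),
  "rbio2.2" = list(
    dec_lo = c(
      0.0, 0.0, 0.3535533905932738, 0.7071067811865476, 0.3535533905932738,
      0.0),
    rec_lo = c(
      -0.1767766952966369, 0.3535533905932738, 1.0606601717798212,
      0.3535533905932738, -0.1767766952966369, 0.0)
  ),
  "rbio2.4" = list(
    dec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.3535533905932738, 0.7071067811865476,
      0.3535533905932738, 0.0, 0.0, 0.0),
    rec_lo = c(
      0.03314563036811941, -0.06629126073623882, -0.1767766952966369,
      0.4198446513295126, 0.9943689110435825, 0.4198446513295126,
      -0.1767766952966369, -0.06629126073623882, 0.03314563036811941, 0.0)
  ),
  "rbio2.6" = list(
    dec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.3535533905932738, 0.7071067811865476,
      0.3535533905932738, 0.0, 0.0, 0.0, 0.0, 0.0),
    rec_lo = c(
      -0.006905339660024878, 0.013810679320049757, 0.04695630968816917,
      -0.1077232986963881, -0.16987135563661201, 0.4474660099696121,
      0.966747552403483, 0.4474660099696121, -0.16987135563661201,
      -0.1077232986963881, 0.04695630968816917, 0.013810679320049757,
      -0.006905339660024878, 0.0)
  ),
  "rbio2.8" = list(
    dec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.3535533905932738,
      0.7071067811865476, 0.3535533905932738, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0,
      0.0),
    rec_lo = c(
      0.0015105430506304422, -0.0030210861012608843, -0.012947511862546647,
      0.02891610982635418, 0.05299848189069094, -0.13491307360773605,
      -0.16382918343409023, 0.46257144047591653, 0.9516421218971786,
      0.46257144047591653, -0.16382918343409023, -0.13491307360773605,
      0.05299848189069094, 0.02891610982635418, -0.012947511862546647,
      -0.0030210861012608843, 0.0015105430506304422, 0.0)
  ),
  "rbio3.1" = list(
    dec_lo = c(
      0.1767766952966369, 0.5303300858899106, 0.5303300858899106,
      0.1767766952966369),
    rec_lo = c(
      -0.3535533905932738, 1.0606601717798212, 1.0606601717798212,
      -0.3535533905932738)
  ),
  "rbio3.3" = list(
    dec_lo = c(
      0.0, 0.0, 0.1767766952966369, 0.5303300858899106, 0.5303300858899106,
      0.1767766952966369, 0.0, 0.0),
    rec_lo = c(
      0.06629126073623882, -0.1988737822087165, -0.15467960838455727,
      0.9943689110435825, 0.9943689110435825, -0.15467960838455727,
      -0.1988737822087165, 0.06629126073623882)
  ),
  "rbio3.5" = list(
    dec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.1767766952966369, 0.5303300858899106,
      0.5303300858899106, 0.1767766952966369, 0.0, 0.0, 0.0, 0.0),
    rec_lo = c(
      -0.013810679320049757, 0.04143203796014927, 0.052480581416189075,
      -0.26792717880896527, -0.07181553246425873, 0.966747552403483,
      0.966747552403483, -0.07181553246425873, -0.26792717880896527,
      0.052480581416189075, 0.04143203796014927, -0.013810679320049757)
  ),
  "rbio3.7" = list(
    dec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.1767766952966369, 0.5303300858899106,
      0.5303300858899106, 0.1767766952966369, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0),
    rec_lo = c(
      0.0030210861012608843, -0.009063258303782653, -0.01683176542131064,
      0.074663985074019, 0.03133297870736289, -0.301159125922835,
      -0.02649924094534547, 0.9516421218971786, 0.9516421218971786,
      -0.02649924094534547, -0.301159125922835, 0.03133297870736289,
      0.074663985074019, -0.01683176542131064, -0.009063258303782653,
      0.0030210861012608843)
  ),
  "rbio3.9" = list(
    dec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.1767766952966369,
      0.5303300858899106, 0.5303300858899106, 0.1767766952966369, 0.0, 0.0,
      0.0, 0.0, 0.0, 0.0, 0.0, 0.0),
    rec_lo = c(
      -0.0006797443727836989, 0.002039233118351097, 0.005060319219611981,
      -0.020618912641105536, -0.014112787930175844, 0.09913478249423216,
      0.012300136269419315, -0.32019196836077857, 0.0020500227115698858,
      0.9421257006782068, 0.9421257006782068, 0.0020500227115698858,
      -0.32019196836077857, 0.012300136269419315, 0.09913478249423216,
      -0.014112787930175844, -0.020618912641105536, 0.005060319219611981,
      0.002039233118351097, -0.0006797443727836989)
  ),
  "rbio4.4" = list(
    dec_lo = c(
      0.0, 0.0, -0.06453888262869706, -0.04068941760916406,
      0.41809227322161724, 0.7884856164055829, 0.41809227322161724,
      -0.04068941760916406, -0.06453888262869706, 0.0),
    rec_lo = c(
      0.03782845550726404, -0.023849465019556843, -0.11062440441843718,
      0.37740285561283066, 0.8526986790088938, 0.37740285561283066,
      -0.11062440441843718, -0.023849465019556843, 0.03782845550726404, 0.0)
  ),
  "rbio5.5" = list(
    dec_lo = c(
      0.0, 0.013456709459118716, -0.002694966880111507, -0.13670658466432914,
      -0.09350469740093886, 0.47680326579848425, 0.8995061097486484,
      0.47680326579848425, -0.09350469740093886, -0.13670658466432914,
      -0.002694966880111507, 0.013456709459118716),
    rec_lo = c(
      0.0, 0.03968708834740544, 0.007948108637240322, -0.05446378846823691,
      0.34560528195603346, 0.7366601814282105, 0.34560528195603346,
      -0.05446378846823691, 0.007948108637240322, 0.03968708834740544, 0.0,
      0.0)
  ),
  "rbio6.8" = list(
    dec_lo = c(
      0.0, 0.0, 0.0, 0.0, 0.014426282505624435, 0.014467504896790148,
      -0.07872200106262882, -0.04036797903033992, 0.41784910915027457,
      0.7589077294536541, 0.41784910915027457, -0.04036797903033992,
      -0.07872200106262882, 0.014467504896790148, 0.014426282505624435, 0.0,
      0.0, 0.0),
    rec_lo = c(
      0.0019088317364812906, -0.0019142861290887667, -0.016990639867602342,
      0.01193456527972926, 0.04973290349094079, -0.07726317316720414,
      -0.09405920349573646, 0.4207962846098268, 0.8259229974584023,
      0.4207962846098268, -0.09405920349573646, -0.07726317316720414,
      0.04973290349094079, 0.01193456527972926, -0.016990639867602342,
      -0.0019142861290887667, 0.0019088317364812906, 0.0)
  )
)
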