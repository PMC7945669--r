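accession
AF407040.1
AF526472.1
AF526476.1
AF526478.1
AF526486.1
AF526496.1
AF526498.1
AH011269.2
AH011270.2
AH011271.2
AH011272.2
AH011273.2
AH011274.2
AH011275.2
AH011276.2
AH011277.2
AH011278.2
AH011279.2
AH011280.2
AH011281.2
AH011282.2
AH011283.2
AH011284.2
AH011285.2
AH011286.2
AH011287.2
AH011288.2
AH011289.2
AH011290.2
AH011291.2
AH011292.2
AH011293.2
AH011294.2
AH011295.2
AH011296.2
AH011297.2
AY156131.1
AY156132.1
AY156133.1
AY156134.1
AY681496.1
AY681497.1
AY681498.1
AY681499.1
AY681500.1
AY681501.1
AY681502.1
AY681503.1
AY681504.1
AY681505.1
AY681506.1
AY681507.1
AY681508.1
AY681509.1
AY681510.1
AY681511.1
AY681512.1
AY681513.1
AY681514.1
AY681515.1
AY681516.1
AY681517.1
AY681518.1
AY681519.1
AY681520.1
AY681521.1
AY681522.1
AY681523.1
AY681524.1
AY681533.1
AY681534.1
AY681535.1
AY681536.1
AY681537.1
AY681538.1
AY681539.1
AY681540.1
AY681541.1
AY681542.1
AY681543.1
AY681544.1
AY681545.1
AY681546.1
AY681547.1
AY681548.1
AY681549.1
AY681550.1
AY681551.1
AY681552.1
AY681553.1
AY681554.1
AY681555.1
AY681556.1
AY681557.1
AY681558.1
AY681559.1
AY681560.1
AY681561.1
AY681562.1
AY681568.1
AY681571.1
AY681572.1
AY681573.1
AY681574.1
AY681575.1
AY681576.1
AY681577.1
AY681578.1
AY681579.1
AY681580.1
AY681581.1
AY681582.1
AY681583.1
AY681584.1
AY681585.1
AY681586.1
AY681587.1
AY681588.1
AY681589.1
AY681590.1
AY681591.1
AY681595.1
AY681596.1
AY681597.1
AY681598.1
AY681599.1
AY681600.1
AY681601.1
AY681602.1
AY681603.1
AY681604.1
AY681605.1
AY681606.1
AY681607.1
AY681608.1
AY681609.1
AY681610.1
AY681611.1
AY681612.1
AY681613.1
AY681614.1
AY681615.1
AY681616.1
AY681617.1
AY681618.1
AY681619.1
AY681620.1
AY681621.1
AY681622.1
AY681623.1
AY681624.1
AY681625.1
AY681626.1
AY681627.1
AY681628.1
AY681629.1
AY681630.1
AY681631.1
AY681632.1
AY681633.1
AY681634.1
AY681635.1
AY681636.1
AY681637.1
AY681638.1
AY681639.1
AY681640.1
AY681641.1
AY681642.1
AY681643.1
AY681644.1
AY681645.1
AY681646.1
AY681647.1
AY681648.1
AY681649.1
AY681650.1
AY681651.1
AY681652.1
AY681653.1
AY681654.1
AY681655.1
AY681656.1
AY681657.1
AY681658.1
AY681659.1
AY681660.1
AY681661.1
AY681662.1
AY681663.1
AY681664.1
AY681665.1
AY681666.1
AY681667.1
AY681668.1
AY681669.1
AY681670.1
AY681671.1
AY681672.1
AY681673.1
AY681674.1
AY681675.1
AY681676.1
AY681677.1
AY681678.1
AY681679.1
AY681680.1
AY681681.1
AY681682.1
AY681683.1
AY681684.1
AY681685.1
AY681686.1
AY681687.1
AY681688.1
AY681689.1
AY681690.1
AY681691.1
AY681692.1
AY681693.1
AY681694.1
AY681695.1
AY681696.1
AY681697.1
AY681698.1
AY681699.1
AY681702.1
AY681711.1
AY681728.1
AY681729.1
AY703261.1
AY703262.1
AY703263.1
AY703264.1
AY703265.1
AY703266.1
AY703267.1
AY703268.1
AY703269.1
AY703270.1
AY703271.1
AY703272.1
AY703273.1
AY703274.1
AY703275.1
AY703276.1
AY703277.1
AY703278.1
AY703279.1
AY703280.1
AY703281.1
AY703282.1
AY703283.1
AY703284.1
AY703285.1
AY703286.1
AY703287.1
AY703288.1
AY703289.1
AY703290.1
AY703291.1
AY703292.1
AY703293.1
AY703294.1
AY703295.1
AY703296.1
AY703297.1
AY703298.1
AY703299.1
AY703300.1
AY703301.1
AY703302.1
AY703303.1
AY703304.1
AY703305.1
AY703306.1
AY703307.1
AY703308.1
AY703309.1
AY703310.1
AY703311.1
AY703312.1
AY703313.1
AY703314.1
AY703315.1
AY703316.1
AY703317.1
AY703318.1
AY703319.1
AY703320.1
AY703321.1
AY703322.1
AY703323.1
AY703324.1
AY703325.1
AY703326.1
AY703327.1
AY703328.1
AY703329.1
AY703330.1
AY703331.1
AY703332.1
AY703333.1
AY703334.1
AY703335.1
AY703336.1
AY703337.1
AY703338.1
AY703339.1
AY703340.1
AY703341.1
AY703342.1
AY703343.1
AY703344.1
AY703345.1
AY703346.1
AY703347.1
AY703348.1
AY703349.1
AY703350.1
AY703351.1
AY703352.1
AY703353.1
AY703354.1
AY703355.1
AY703356.1
AY703357.1
AY703358.1
AY703359.1
AY703360.1
AY703361.1
AY703362.1
AY703363.1
AY703364.1
AY703365.1
AY703366.1
AY703367.1
AY703368.1
AY703369.1
AY703370.1
AY703371.1
AY703372.1
AY703373.1
AY703374.1
AY703375.1
AY703376.1
AY703377.1
AY703378.1
AY703379.1
AY703380.1
AY703381.1
AY703382.1
AY703383.1
AY703384.1
AY703385.1
AY703386.1
AY703387.1
AY703388.1
AY703389.1
AY703390.1
AY703391.1
AY703392.1
AY703393.1
AY703394.1
AY703395.1
AY703396.1
AY703397.1
AY703398.1
AY703399.1
AY703400.1
AY703401.1
AY703402.1
AY703403.1
AY703404.1
AY703405.1
AY703406.1
AY703407.1
AY703408.1
AY703409.1
AY703410.1
AY703411.1
AY703412.1
AY703413.1
AY703414.1
AY703415.1
AY703416.1
AY703417.1
AY703418.1
AY703419.1
AY703420.1
AY703421.1
AY703422.1
AY703423.1
AY703424.1
AY703425.1
AY703426.1
AY703427.1
AY703428.1
AY703429.1
AY703430.1
AY703431.1
AY703432.1
AY703433.1
AY703434.1
AY703435.1
AY703436.1
AY703437.1
AY703438.1
AY703439.1
AY703440.1
AY703441.1
AY703442.1
AY703443.1
AY703444.1
AY703445.1
AY703446.1
DQ188164.1
EU166960.1
FJ547513.1
FJ547514.1
FJ547515.1
FJ547516.1
FJ547517.1
GQ870799.1
GQ870800.1
GQ870801.1
GQ870802.1
GQ870803.1
GQ870804.1
GQ870805.1
GQ870806.1
GQ870807.1
GQ870808.1
GQ870809.1
GQ870810.1
GQ870811.1
GQ870812.1
GQ870813.1
GQ870814.1
GQ870815.1
GQ870816.1
GQ870817.1
GQ870818.1
GQ870819.1
GQ870820.1
GQ870821.1
GQ870822.1
GQ870823.1
GQ870824.1
GQ870825.1
GQ870826.1
GQ870827.1
GQ870828.1
GQ870829.1
GQ870830.1
GQ870831.1
GQ870832.1
GQ870833.1
GQ870834.1
GQ870835.1
GQ870836.1
GQ870837.1
GQ870838.1
GQ870839.1
GQ870840.1
GQ870841.1
GQ870842.1
GQ870843.1
GQ870844.1
GQ870845.1
GQ870846.1
GQ870847.1
GQ870848.1
GQ870849.1
GQ870850.1
GQ870851.1
GQ870852.1
GQ870853.1
GQ870854.1
GQ870855.1
GQ870856.1
GQ870857.1
GQ870858.1
GQ870859.1
GQ870860.1
GQ870861.1
GQ870862.1
GQ870863.1
GQ870864.1
GQ870865.1
GQ870866.1
GQ870867.1
GU816849.1
JN715428.1
JN715468.1
KC759308.1
KC969098.1
KF194129.1
KF194140.1
KF194157.1
KJ455349.1
KJ455507.1
KM078781.1
KP765391.1
KP765392.1
KP765393.1
KP765394.1
KP765395.1
KP765396.1
KP765397.1
KP765398.1
KP765399.1
KP765400.1
KP765401.1
KP765402.1
KT031286.1
KT031292.1
KT031305.1
KT031306.1
KT031307.1
KT031308.1
KT031309.1
KT031310.1
KT031311.1
KT031312.1
KT031313.1
KT031314.1
KT031315.1
KT031316.1
KT031317.1
KT031318.1
KT031319.1
KT031320.1
KT031321.1
KT031322.1
KT031323.1
KT031324.1
KT031325.1
KT031326.1
KT031331.1
KT736087.1
NC_025609.1
NC_029229.1
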