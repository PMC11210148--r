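# R-R intervals [ms], one per line
888.03500396509878
900.43426130505145
938.13283563858874
941.31749846073501
890.92429924916405
846.58888974315857
878.52557044510127
911.21265794327826
918.11426658094456
883.30493371934722
906.0768231200467
959.39727666989756
969.60138992790621
910.46685694600285
891.98048243099174
913.49788877241951
944.15081459509349
908.37810301125501
860.6755539458826
903.30714418462242
961.73853286284839
954.84526857695687
918.36557468180581
933.24443133002637
972.33110261257445
948.77249478950318
907.28370907070541
889.90454193782398
927.25003783039165
951.44325999243017
931.914450395053
915.44662434073871
958.39244526654261
1004.1929284869111
974.47480009303115
912.33045887367325
936.95149375383119
961.16722124756541
940.50710811558008
899.69273581046309
911.60422306032035
964.75540350110305
983.67676604094322
952.02591610713273
943.63157531794764
970.48499041684329
978.11794690369629
931.14021148690824
883.93080498480435
924.32805299866379
950.81510831890068
939.17603257754274
912.84982842740953
931.90407995665157
994.79377429234694
983.20505134854898
931.1846794247183
910.19728089219689
959.90153143199359
939.67689472843824
888.62911303969929
890.65522639808285
919.3657612515982
963.29421169121338
941.00482574601028
911.64332657377895
960.00776136562979
960.65460955035462
943.28940052547864
865.76038912542936
887.99523287691022
928.79600235839712
936.38879055184475
893.34254858404688
883.2069178531558
935.42538355393719
968.25702524147835
927.66974723836847
871.91173659819117
893.21854451281467
930.75703476377737
894.15731262140548
849.25916532048359
861.49807673794089
900.4181091479536
942.38900993805851
909.46227122393179
900.38212911779874
916.33376464212711
939.1820463841425
899.10034486876316
836.52794364115539
848.28130984641109
891.43390317688466
904.54073463052748
891.74678228898983
870.00887515924501
904.53301666079221
964.08092184743896
927.28129110387226
880.35072078873327
870.41407797205011
917.17878339637821
898.69841630658789
855.4039690635833
843.19655441378313
881.13675748704588
940.96685932554908
925.75777162630391
889.43915533969709
914.72848914968142
949.95895656211894
937.85337547286213
872.71440025064408
855.34248203267509
886.06588767715107
914.14296652264193
921.66863651165511
874.85560670815357
900.05391212001086
954.63818466638293
957.76544577976017
896.27221239011078
902.24573144189878
931.38872454902298
921.78251918860406
895.90577748430837
873.50688307572887
906.45559934094354
962.12677369344999
946.87175975150444
920.94596517523348
938.82544108114382
970.38239717893475
950.07852438107693
886.92912586457533
878.00184648211473
931.5315736091278
952.62322758588004
918.01754372506639
905.98354612911851
966.62791400051503
991.50836801306968
960.33747508522174
909.5526172180945
910.68216000099142
957.01248922587331
931.00118120814648
884.60831065975106
906.22003761947019
963.66374436020908
980.73942457736121
952.10111453076684
951.05167406281896
969.59553433310089
980.1893343933499
926.9973122910751
884.73322298559992
923.42057847692251
962.04260829388613
942.73145050793573
921.93187242396311
945.88956270738947
989.89423887203554
961.54821047845905
929.25535643293335
918.84781317247132
958.48936217991411
937.39384389959082
889.129909787879
889.29332826656844
941.99707566147151
974.07053538194964
944.47653305562642
919.09086368791338
942.63527049628817
976.9919605281035
937.37579534691361
862.38732409690431
883.42396074028306
924.12252323657833
919.01475492138343
892.14775189959084
895.4571329952588
964.03617612620121
954.24662435547214
924.98912757771416
903.91021930897466
889.74932880052813
926.53271536944817
903.62813216638551
849.22285655296332
874.21938988779914
921.68311534181805
924.68370400176093
908.68197435901789
882.74117653340988
917.60308495178242
941.59393391224012
903.14527509575385
856.7069286760036
851.97067308565238
895.68519448910365
908.64735455086236
880.94021198504993
855.9355728780165
921.17292009354878
950.56501019386224
919.68921177154175
865.00209404277757
881.82915635663176
908.64240014969675
885.21948228780661
854.62412906084194
854.26645819482121
904.25198940096709
953.89256243962802
927.59071813777825
881.71229846710776
920.37055391064962
945.90063916422343
915.93224937141247
872.29047557253807
849.27087764075759
906.12448567760282
917.09040974586355
905.66952633192773
893.65215473125102
932.63203917358339
970.34190513948545
929.23094487916421
891.52337241937244
898.2212433457936
947.28403099168759
917.60706868136219
859.53964249264629
863.47799737658272
933.63839211943628
968.37548766772261
947.89996680865249
907.53004022423238
958.31405947178712
968.74816298464975
921.86456703390854
890.20436509787862
886.07439449253263
940.97415152242263
951.09175252239845
915.21555256314457
927.90672435016643
976.08999869395006
991.45733768790285
950.27948594651787
907.0719853457922
946.80910406272324
948.5438242815444
905.68537733370954
874.00496275108878
918.27682576797997
965.58230671100864
979.40814131073159
932.90248735681769
935.37969467532275
993.12250308770808
985.09868400005098
911.27576903866668
902.03627415103756
926.20740788045589
957.65876952868837
923.67453505388551
931.38450038828205
956.28627920773158
998.58888982325811
965.55924301232506
927.37160372561198
925.66671975528391
957.40276143173048
919.73538707538796
876.60964927103669
879.71540539231137
938.94737864402578
976.86141128994836
933.38521667919872
918.08035914051572
961.27765060858587
962.94851598231799
903.18774783835329
859.0279534659943
884.0832389957601
942.92357645677066
922.88551231610074
898.00450570960834
890.36688925715919
975.84925550369019
969.47184151958652
901.08493467460028
878.0342443963774
907.15626542896655
916.23296281451735
881.1239461689413
840.47876656356812
871.01324880627089
926.10902486518228
939.68382882416813
893.50459660431738
880.88302348875163
927.03211322162622
940.48518549707978
893.37385475655503
826.67581538309457
867.58997002481806
907.26848065347542
906.71072676083713
885.16072594406637
882.15827308960468
919.16973942448078
950.56051264307848
917.01121880890037
865.26618685147264
877.4381276523568
923.6943282086479
890.13685965146419
854.97923074070047
862.72466833623878
912.69179168722042
939.06447898232216
926.5408128520553
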